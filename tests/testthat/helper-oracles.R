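# Independent brute-force oracles: O(n^2) implementations built straight
# from the definitions, sharing no code with the package internals.

# full neighbor ordering of cell i: ascending (Euclidean distance, index)
bruteNeighborOrder <- function(emb, i) {
  d <- sqrt(colSums((t(emb) - emb[i, ])^2))
  ord <- order(d, seq_len(nrow(emb)))
  setdiff(ord, i)
}

# out-edge set of cell i with budget m: self plus the m-1 nearest others
bruteOutEdges <- function(emb, i, m) {
  if (m == 1) return(i)
  c(i, bruteNeighborOrder(emb, i)[seq_len(m - 1)])
}

# per-cell neighborhood connectivity from the definition
bruteCellQ <- function(emb, cell, k) {
  S <- bruteOutEdges(emb, cell, k)
  edges <- 0
  for (i in S) {
    out <- bruteOutEdges(emb, i, k)
    edges <- edges + length(intersect(out, S))
  }
  edges / (k * k)
}

# cluster connectivity with the adaptive budget min(n, kParam)
bruteClusterQ <- function(emb, members, kParam = 20) {
  n <- length(members)
  keff <- min(n, kParam)
  edges <- 0
  for (i in members) {
    out <- bruteOutEdges(emb, i, keff)
    edges <- edges + length(intersect(out, members))
  }
  edges / (n * keff)
}
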