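# shared geometric fixtures, built in code

# n collinear points at x = 0..n-1
lineEmbedding <- function(n = 10) {
  emb <- cbind(x = as.numeric(seq_len(n) - 1), y = 0)
  rownames(emb) <- paste0("c", seq_len(n))
  emb
}

# regular polygons of `size` points (radius r) at well-separated centers
cliqueEmbedding <- function(nCliques = 2, size = 6, r = 0.1, sep = 100) {
  ang <- 2 * pi * seq_len(size) / size
  one <- cbind(r * cos(ang), r * sin(ang))
  emb <- do.call(rbind, lapply(seq_len(nCliques) - 1,
                               function(i) sweep(one, 2, c(i * sep, 0), "+")))
  rownames(emb) <- paste0("c", seq_len(nrow(emb)))
  emb
}

# wrap raw labels in a ClusterAssignment at a given stage
asAssignment <- function(labels, stage = "voted") {
  new("ClusterAssignment", labels = as.integer(labels), stage = stage,
      waypoints = integer(), iterationsUsed = 0L, converged = TRUE)
}
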