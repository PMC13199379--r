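#' Per-cell neighborhood connectivity Q
#'
#' For a cell's neighborhood S (the cell plus its k-1 nearest neighbors), Q
#' is the number of directed kNN edges from members of S that land inside S
#' -- each member contributes its self-edge and its own k-1 nearest
#' out-edges -- divided by the total budget k*k.  Q ranges between 1/k and
#' 1 (structurally it cannot fall below (2k-1)/k^2); values near 1 mark the
#' tight, self-contained cliques characteristic of rare populations.
#'
#' @param index a [NeighborIndex-class]
#' @param cell 1-based cell index
#' @param k neighborhood size (default 6; must not exceed `kParam(index)`)
#' @return a single Q value in `[1/k, 1]`
#' @examples
#' emb <- cbind(x = 0:9, y = 0)
#' idx <- buildKnn(emb, kParam = 4)
#' cellQ(idx, 1, k = 3) # 8/9
#' @export
cellQ <- function(index, cell, k = 6L) {
  S <- neighborhood(index, cell, k)
  k <- as.integer(k)
  if (k == 1L) return(1)
  edges <- k # self-edges of all members
  for (i in S) {
    out <- index@nnIdx[i, seq_len(k - 1L)]
    edges <- edges + sum(out %in% S)
  }
  edges / (k * k)
}

#' Q scores for all cells
#'
#' @inheritParams cellQ
#' @return a [QScores-class]
#' @export
allQ <- function(index, k = 6L) {
  k <- as.integer(k)
  n <- length(index@cellIds)
  if (k > index@kParam) stop("neighborhood exceeds index capacity")
  if (k > n) stop("neighborhood exceeds cell count")
  q <- if (k == 1L) rep(1, n) else .q_scores_cpp(index@nnIdx, k)
  names(q) <- index@cellIds
  new("QScores", q = q, k = k)
}

#' Cluster-level connectivity Qc
#'
#' Extends Q to a whole cluster C of n cells: every member contributes its
#' self-edge and its keff - 1 nearest out-edges, where the effective budget
#' keff is n when n < kParam and kParam otherwise (with the default
#' capacity 20 this is the published n-vs-20 rule); the count of internal
#' edges is divided by n * keff.  Qc ranges between 1/keff and 1.
#'
#' @param index a [NeighborIndex-class]
#' @param members integer vector of 1-based cell indices (non-empty, no
#'   duplicates)
#' @return a single Qc value
#' @examples
#' emb <- cbind(x = 0:3, y = 0)
#' idx <- buildKnn(emb, kParam = 4)
#' clusterQ(idx, c(2, 3)) # 3/4
#' @export
clusterQ <- function(index, members) {
  members <- as.integer(members)
  if (length(members) == 0L) stop("empty cluster")
  if (anyDuplicated(members)) stop("duplicate members")
  n <- length(members)
  keff <- min(n, index@kParam)
  if (keff == 1L) return(1)
  .cluster_q_cpp(index@nnIdx, members, keff)
}

#' Effective per-member edge budget of a cluster
#'
#' @param n cluster size
#' @param kParam neighbor-list capacity (default 20)
#' @return `min(n, kParam)`
#' @export
kParamEff <- function(n, kParam = 20L) pmin(as.integer(n), as.integer(kParam))

#' Per-cluster statistics
#'
#' @param index a [NeighborIndex-class]
#' @param labels per-cell cluster labels
#' @param q a [QScores-class] computed on the same index
#' @return data.frame with columns cluster, n, kParamEff, meanQ, qC
#' @export
computeClusterStats <- function(index, labels, q) {
  stopifnot(length(labels) == length(index@cellIds))
  qv <- qValues(q)
  ids <- sort(unique(labels))
  rows <- lapply(ids, function(cl) {
    mem <- which(labels == cl)
    data.frame(cluster = cl, n = length(mem),
               kParamEff = kParamEff(length(mem), index@kParam),
               meanQ = mean(qv[mem]), qC = clusterQ(index, mem))
  })
  do.call(rbind, rows)
}

#' @rdname QScores-class
#' @export
setMethod("qValues", "QScores", function(x) x@q)

#' @rdname QScores-class
#' @export
setMethod("neighborhoodSize", "QScores", function(x) x@k)

setMethod("show", "QScores", function(object) {
  cat("QScores:", length(object@q), "cells, k =", object@k,
      sprintf("| range [%.3f, %.3f]\n", min(object@q), max(object@q)))
})
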