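#' Build the directed kNN graph on an embedding
#'
#' Computes, for every cell, its `kParam - 1` nearest other cells by
#' Euclidean distance in the embedding, ordered ascending with equal
#' distances broken toward the smaller cell index.  The resulting
#' [NeighborIndex-class] defines the edge convention used by every other
#' function: cell `i` has a directed edge to itself and to each cell on its
#' neighbor list (truncated to the budget of the query at hand).
#'
#' Below `exactThreshold` cells the search is an exact full scan; above it
#' an approximate kd-tree search (RANN) is used and the result is flagged
#' `approximate`.  Exact mode is a deterministic, bit-reproducible function
#' of `(embedding, kParam)`.
#'
#' @param embedding numeric matrix, cells x dimensions, with unique
#'   rownames as cell ids (generated `cell1..cellN` when absent).
#' @param kParam integer neighbor-list capacity counting the implicit self
#'   (default 20).
#' @param exactThreshold cell count above which approximate search is used
#'   (default 50000).
#' @return a [NeighborIndex-class]
#' @examples
#' emb <- cbind(x = 0:9, y = 0)
#' idx <- buildKnn(emb, kParam = 4)
#' neighborMatrix(idx)[1, ] # cells 2, 3, 4 (1-based)
#' @export
buildKnn <- function(embedding, kParam = 20L, exactThreshold = 50000L) {
  embedding <- as.matrix(embedding)
  storage.mode(embedding) <- "double"
  n <- nrow(embedding)
  if (n < 2L) stop("insufficient cells: need at least 2")
  kParam <- as.integer(kParam)
  if (is.na(kParam) || kParam < 2L) stop("invalid k_param: must be >= 2")
  if (!all(is.finite(embedding))) stop("invalid embedding: non-finite values")
  ids <- rownames(embedding)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  if (anyDuplicated(ids)) stop("invalid embedding: duplicated cell ids")

  m <- min(kParam - 1L, n - 1L)
  approx <- n > exactThreshold
  if (approx) {
    if (!requireNamespace("RANN", quietly = TRUE))
      stop("approximate search requires the RANN package")
    nn <- RANN::nn2(embedding, k = m + 1L, searchtype = "priority",
                    eps = 0.1)
    idx <- nn$nn.idx
    dst <- nn$nn.dists
    # drop self wherever it appears in the candidate list
    keep <- t(vapply(seq_len(n), function(i) {
      row <- idx[i, ]
      j <- which(row == i)[1]
      if (is.na(j)) seq_len(m) else setdiff(seq_len(m + 1L), j)[seq_len(m)]
    }, integer(m)))
    idx <- matrix(idx[cbind(rep(seq_len(n), m), as.vector(keep))], n, m)
    dst <- matrix(dst[cbind(rep(seq_len(n), m), as.vector(keep))], n, m)
  } else {
    # both paths are exact with ascending (distance, index) ordering; the
    # blocked path generates candidates by BLAS and re-refines them
    # coordinate-wise, so results are identical to the full scan
    res <- if (n > 2048L) .exact_knn_blocked_cpp(embedding, m)
           else .exact_knn_cpp(embedding, m)
    idx <- res$idx
    dst <- res$dist
  }
  new("NeighborIndex", cellIds = ids, nnIdx = idx, nnDist = dst,
      kParam = kParam, approximate = approx)
}

#' Neighborhood of a cell
#'
#' The ordered set S of `k` cells made of `cell` itself followed by its
#' `k - 1` nearest neighbors.
#'
#' @param index a [NeighborIndex-class]
#' @param cell 1-based cell index
#' @param k neighborhood size, `1 <= k <= kParam(index)`
#' @return integer vector of length `k`
#' @export
neighborhood <- function(index, cell, k) {
  k <- as.integer(k)
  n <- length(index@cellIds)
  if (k > index@kParam) stop("neighborhood exceeds index capacity")
  if (k > n) stop("neighborhood exceeds cell count")
  if (k < 1L) stop("k must be >= 1")
  cell <- as.integer(cell)
  if (cell < 1L || cell > n) stop("cell index out of range")
  if (k == 1L) return(cell)
  c(cell, index@nnIdx[cell, seq_len(k - 1L)])
}

#' @describeIn buildKnn save a NeighborIndex to an RDS cache file
#' @param index a [NeighborIndex-class]
#' @param path file path
#' @export
saveNeighborIndex <- function(index, path) {
  stopifnot(is(index, "NeighborIndex"))
  saveRDS(list(cellIds = index@cellIds, nnIdx = index@nnIdx,
               nnDist = index@nnDist, kParam = index@kParam,
               approximate = index@approximate), path)
  invisible(path)
}

#' @describeIn buildKnn load a NeighborIndex from an RDS cache file
#' @export
readNeighborIndex <- function(path) {
  x <- readRDS(path)
  new("NeighborIndex", cellIds = x$cellIds, nnIdx = x$nnIdx,
      nnDist = x$nnDist, kParam = x$kParam, approximate = x$approximate)
}

#' @rdname NeighborIndex-class
#' @export
setMethod("cellIds", "NeighborIndex", function(x) x@cellIds)

#' @rdname NeighborIndex-class
#' @export
setMethod("kParam", "NeighborIndex", function(x) x@kParam)

#' @rdname NeighborIndex-class
#' @export
setMethod("neighborMatrix", "NeighborIndex", function(x) x@nnIdx)

#' @rdname NeighborIndex-class
#' @export
setMethod("neighborDistances", "NeighborIndex", function(x) x@nnDist)

#' @rdname NeighborIndex-class
#' @export
setMethod("isApproximate", "NeighborIndex", function(x) x@approximate)

setMethod("show", "NeighborIndex", function(object) {
  cat("NeighborIndex:", length(object@cellIds), "cells, kParam =",
      object@kParam,
      if (object@approximate) "(approximate)" else "(exact)", "\n")
})
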