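#' Library-size log-normalization
#'
#' Scales every cell to a common total, multiplies by `scaleFactor` and
#' applies log1p: entry (c, g) becomes
#' `log(1 + scaleFactor * counts[c, g] / total[c])`.  Zero counts stay
#' zero, so sparsity is preserved.  The result is invariant to per-cell
#' sequencing depth.
#'
#' @param counts cells x genes matrix (base or Matrix), non-negative
#' @param scaleFactor positive scale (default 10000; use 80 for
#'   low-feature spatial panels)
#' @return normalized matrix of the same class and dimnames
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
  stopifnot(scaleFactor > 0)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) stop("empty cell: a cell has zero total counts")
  if (inherits(counts, "sparseMatrix")) {
    out <- Matrix::Diagonal(x = scaleFactor / tot) %*% counts
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(scaleFactor * counts / tot)
  }
}

#' Select highly variable genes by standardized dispersion
#'
#' Works on the log-normalized matrix: per-gene mean and variance are
#' computed on the de-logged (expm1) values, dispersion is variance/mean,
#' and log-dispersions are z-scored within 20 equal-frequency bins of the
#' mean so that the ranking is not driven by expression level.  Genes are
#' ranked by standardized dispersion, ties broken by gene order.  Genes
#' with zero mean or zero variance rank last.
#'
#' @param normalized cells x genes log-normalized matrix with gene colnames
#' @param nHvg number of genes to return, or `"all"` (the low-feature
#'   spatial-panel path)
#' @param nBins number of mean bins for standardization (default 20)
#' @return character vector of selected gene ids
#' @export
selectHVG <- function(normalized, nHvg = 2000L, nBins = 20L) {
  genes <- colnames(normalized)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(normalized)))
  if (identical(nHvg, "all")) return(genes)
  nHvg <- as.integer(nHvg)
  stopifnot(nHvg >= 1L, nHvg <= ncol(normalized))
  x <- expm1(normalized)
  n <- nrow(x)
  mu <- as.vector(Matrix::colMeans(x))
  ex2 <- as.vector(Matrix::colMeans(x^2))
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0
  disp <- ifelse(mu > 0 & v > 0, v / mu, NA_real_)
  z <- rep(-Inf, length(mu))
  ok <- !is.na(disp)
  if (any(ok)) {
    bins <- as.integer(cut(rank(mu[ok], ties.method = "first"),
                           breaks = min(nBins, sum(ok)), labels = FALSE))
    ld <- log(disp[ok])
    zo <- ld
    for (b in unique(bins)) {
      i <- bins == b
      s <- stats::sd(ld[i])
      zo[i] <- if (is.na(s) || s == 0) 0 else (ld[i] - mean(ld[i])) / s
    }
    z[ok] <- zo
  }
  genes[order(-z, seq_along(z))][seq_len(nHvg)]
}

#' PCA embedding of selected genes
#'
#' Standardizes the selected genes to zero mean and unit variance, clips
#' standardized values at +/- `clipMax`, and projects onto the top `nPcs`
#' principal components (eigendecomposition of the gene-gene covariance).
#' Component signs are fixed so that each component's largest-magnitude
#' gene loading is positive, making the embedding a deterministic function
#' of the input and invariant to gene order.
#'
#' @param normalized cells x genes log-normalized matrix
#' @param genes gene ids to use (e.g. from [selectHVG()]); `NULL` = all
#' @param nPcs number of components (default 50)
#' @param clipMax clip bound on standardized values (default 10)
#' @return numeric matrix cells x nPcs with cell rownames
#' @export
pcaEmbed <- function(normalized, genes = NULL, nPcs = 50L, clipMax = 10) {
  if (!is.null(genes)) normalized <- normalized[, genes, drop = FALSE]
  X <- as.matrix(normalized)
  nPcs <- as.integer(nPcs)
  if (nPcs > min(dim(X))) stop("rank deficient: nPcs exceeds matrix rank")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- Inf # constant genes contribute nothing
  X <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  X[X > clipMax] <- clipMax
  X[X < -clipMax] <- -clipMax
  # order-invariant covariance eigendecomposition
  cov <- crossprod(X) / (nrow(X) - 1)
  eig <- eigen(cov, symmetric = TRUE)
  V <- eig$vectors[, seq_len(nPcs), drop = FALSE]
  flip <- vapply(seq_len(nPcs), function(j) {
    l <- V[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  V <- sweep(V, 2, flip, "*")
  scores <- X %*% V
  colnames(scores) <- paste0("PC", seq_len(nPcs))
  rownames(scores) <- rownames(normalized)
  scores
}

#' Counts-to-embedding preprocessing chain
#'
#' log-normalize, select highly variable genes, scale and PCA-embed: the
#' standard route from a raw UMI count matrix to the low-dimensional space
#' the kNN graph is built in.
#'
#' @param counts cells x genes count matrix
#' @param scaleFactor normalization scale (default 10000)
#' @param nHvg highly variable gene count or "all" (default 2000, capped
#'   at the gene count)
#' @param nPcs principal components (default 50, capped at the matrix rank)
#' @param clipMax standardized-value clip (default 10)
#' @return embedding matrix suitable for [buildKnn()] / [runRareQ()]
#' @export
preprocessCounts <- function(counts, scaleFactor = 1e4, nHvg = 2000L,
                             nPcs = 50L, clipMax = 10) {
  norm <- logNormalize(counts, scaleFactor)
  if (!identical(nHvg, "all")) nHvg <- min(as.integer(nHvg), ncol(norm))
  genes <- selectHVG(norm, nHvg)
  nPcs <- min(as.integer(nPcs), length(genes), nrow(norm))
  pcaEmbed(norm, genes, nPcs, clipMax)
}
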