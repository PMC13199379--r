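# All generators are pure functions of their parameters and seed: they run
# under a local RNG state (withr-style) and never touch the caller's.

.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Largest-remainder integer allocation
#'
#' Distributes `total` units over categories proportionally to `weights`:
#' floors of the exact quotas first, leftover units to the largest
#' fractional remainders (ties by category order).
#'
#' @param total integer to allocate
#' @param weights non-negative weights
#' @return integer vector summing to `total`
#' @export
largestRemainder <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Gaussian embedding blobs with planted type labels
#'
#' One isotropic unit-variance Gaussian cloud per type, centers placed at
#' `separation` along distinct coordinate axes (random unit directions at
#' radius `separation` once the types outnumber the dimensions), so any
#' two axis-placed centers are `separation * sqrt(2)` within-type standard
#' deviations apart.  Per-type cell counts follow largest-remainder
#' allocation of the proportions.
#'
#' @param nCells total cell count
#' @param proportions named (or unnamed) positive type proportions summing
#'   to 1
#' @param separation center distance scale in units of within-type sd
#'   (default 10 = well separated; 0 = one mixed cloud)
#' @param dim embedding dimension (default 10)
#' @param seed RNG seed
#' @return list(embedding = cells x dim matrix with cell-id rownames,
#'   labels = named character vector of true types)
#' @export
makeBlobs <- function(nCells, proportions, separation = 10, dim = 10L,
                      seed = 1L) {
  stopifnot(all(proportions > 0), abs(sum(proportions) - 1) < 1e-8)
  if (any(nCells * proportions < 1)) stop("rare type too small")
  tnames <- names(proportions)
  if (is.null(tnames)) tnames <- paste0("type", seq_along(proportions))
  counts <- largestRemainder(nCells, proportions)
  .withSeed(seed, {
    nt <- length(proportions)
    centers <- matrix(0, nt, dim)
    for (t in seq_len(nt)) {
      if (t <= dim) {
        centers[t, t] <- separation
      } else {
        u <- stats::rnorm(dim)
        centers[t, ] <- separation * u / sqrt(sum(u^2))
      }
    }
    coords <- matrix(stats::rnorm(nCells * dim), nCells, dim)
    labels <- rep(tnames, counts)
    coords <- coords + centers[rep(seq_len(nt), counts), , drop = FALSE]
    ids <- paste0("cell", seq_len(nCells))
    rownames(coords) <- ids
    list(embedding = coords, labels = stats::setNames(labels, ids))
  })
}

#' Gamma-Poisson count simulation with group-wise DE factors
#'
#' A splatter-style generative model: gene base means are Gamma
#' distributed; within each group a gene is differentially expressed with
#' probability `deProb`, its mean multiplied by a log-normal factor
#' (log-mean `deFacLoc`, log-sd `deFacScale`, sign of the log-factor
#' symmetric so up- and down-regulation are equally likely); per-cell
#' library sizes are log-normal; counts are Poisson with rate
#' `library * groupMean / sum(groupMean)`.  Group membership is
#' multinomial over `groupProb` unless `groupSizes` forces exact counts.
#'
#' @param nGenes gene count (default 5000)
#' @param groupProb group probabilities summing to 1 (default
#'   `c(0.99, 0.01)`)
#' @param batchCells total cell count (default 1500)
#' @param deProb per-group DE probability, recycled (default 0.4)
#' @param deFacLoc,deFacScale log-normal DE-factor location and scale
#'   (defaults 0.4 and 0.8)
#' @param outProb expression-outlier probability; only 0 is supported
#' @param libLoc,libScale log-normal library-size parameters (defaults 11
#'   and 0.2)
#' @param meanShape,meanRate Gamma parameters of gene base means (defaults
#'   0.6 and 0.3)
#' @param groupSizes optional exact per-group cell counts overriding the
#'   multinomial draw
#' @param seed RNG seed
#' @return list(counts = cells x genes matrix, labels = named character
#'   ("group1", ...), geneMeans = base means, deFactors = genes x groups
#'   factor matrix)
#' @export
simulateCounts <- function(nGenes = 5000L, groupProb = c(0.99, 0.01),
                           batchCells = 1500L, deProb = 0.4,
                           deFacLoc = 0.4, deFacScale = 0.8, outProb = 0,
                           libLoc = 11, libScale = 0.2, meanShape = 0.6,
                           meanRate = 0.3, groupSizes = NULL, seed = 1L) {
  if (any(groupProb < 0) || any(groupProb > 1) ||
      abs(sum(groupProb) - 1) > 1e-8)
    stop("invalid params: groupProb must be probabilities summing to 1")
  nGroups <- length(groupProb)
  deProb <- rep_len(deProb, nGroups)
  if (any(deProb < 0 | deProb > 1)) stop("invalid params: deProb")
  if (outProb != 0) stop("not implemented: outProb > 0")
  .withSeed(seed, {
    if (is.null(groupSizes)) {
      grp <- sample.int(nGroups, batchCells, replace = TRUE,
                        prob = groupProb)
    } else {
      stopifnot(length(groupSizes) == nGroups,
                sum(groupSizes) == batchCells)
      grp <- rep(seq_len(nGroups), groupSizes)
    }
    baseMean <- stats::rgamma(nGenes, shape = meanShape, rate = meanRate)
    deFac <- matrix(1, nGenes, nGroups)
    for (g in seq_len(nGroups)) {
      isDe <- stats::runif(nGenes) < deProb[g]
      nde <- sum(isDe)
      if (nde > 0) {
        lf <- stats::rnorm(nde, mean = deFacLoc, sd = deFacScale)
        dn <- stats::runif(nde) < 0.5
        lf[dn] <- -lf[dn]
        deFac[isDe, g] <- exp(lf)
      }
    }
    lib <- stats::rlnorm(batchCells, meanlog = libLoc, sdlog = libScale)
    groupMean <- baseMean * deFac # genes x groups
    groupProp <- sweep(groupMean, 2, colSums(groupMean), "/")
    rate <- lib * t(groupProp[, grp, drop = FALSE]) # cells x genes
    counts <- matrix(stats::rpois(length(rate), as.vector(rate)),
                     nrow = batchCells, ncol = nGenes)
    ids <- paste0("cell", seq_len(batchCells))
    gids <- paste0("gene", seq_len(nGenes))
    dimnames(counts) <- list(ids, gids)
    rownames(deFac) <- gids
    list(counts = counts,
         labels = stats::setNames(paste0("group", grp), ids),
         geneMeans = stats::setNames(baseMean, gids), deFactors = deFac)
  })
}

#' Label-stratified down-sampling with fixed rare counts
#'
#' Samples a subset of cells so that every rare type contributes exactly
#' `rareCount` cells while the remaining budget is split over the major
#' types proportionally to their source frequencies (largest-remainder
#' rounding).  With `rareCount = NULL` all listed types, rare included,
#' are allocated proportionally.
#'
#' @param labels per-cell type labels of the source dataset
#' @param majorTypes,rareTypes type names to sample from
#' @param total total cells to draw
#' @param rareCount exact cells per rare type, or `NULL` for proportional
#' @param seed RNG seed
#' @return sorted integer vector of selected cell indices
#' @export
downsampleByType <- function(labels, majorTypes, rareTypes, total,
                             rareCount = 50L, seed = 1L) {
  labels <- as.character(labels)
  types <- c(majorTypes, rareTypes)
  stopifnot(!anyDuplicated(types), all(types %in% labels))
  avail <- table(labels)[types]
  if (is.null(rareCount)) {
    quota <- largestRemainder(total, as.vector(avail))
  } else {
    rareQuota <- rep(as.integer(rareCount), length(rareTypes))
    majorBudget <- total - sum(rareQuota)
    if (majorBudget < 0) stop("cannot satisfy quota: rare counts exceed total")
    quota <- c(largestRemainder(majorBudget,
                                as.vector(avail[majorTypes])), rareQuota)
  }
  names(quota) <- types
  if (any(quota > as.vector(avail)))
    stop("cannot satisfy quota: insufficient cells of some type")
  .withSeed(seed, {
    picks <- lapply(types, function(tp) {
      pool <- which(labels == tp)
      pool[sample.int(length(pool), quota[[tp]])]
    })
    sort(unlist(picks))
  })
}

#' DEG titration by gene replacement
#'
#' Starting from a null (no-DE) count matrix, overwrites `r` randomly
#' chosen genes with `r` randomly chosen genes from a pre-identified DEG
#' pool (cells aligned by position).  The random choices are nested: with
#' a fixed seed, the genes replaced at level r are a subset of those
#' replaced at any r' > r, so titration curves are monotone by
#' construction.
#'
#' @param nullCounts cells x genes matrix without differential expression
#' @param degCounts cells x genes matrix holding the DEG pool (same cells)
#' @param r number of genes to replace
#' @param seed RNG seed
#' @return the titrated cells x genes matrix (replaced columns renamed to
#'   the DEG ids)
#' @export
degTitration <- function(nullCounts, degCounts, r, seed = 1L) {
  stopifnot(nrow(nullCounts) == nrow(degCounts))
  r <- as.integer(r)
  if (r > ncol(degCounts) || r > ncol(nullCounts))
    stop("titration exceeds pool")
  .withSeed(seed, {
    replaceOrd <- sample.int(ncol(nullCounts))
    poolOrd <- sample.int(ncol(degCounts))
    out <- nullCounts
    if (r > 0) {
      ri <- replaceOrd[seq_len(r)]
      pi_ <- poolOrd[seq_len(r)]
      out[, ri] <- as.matrix(degCounts[, pi_, drop = FALSE])
      cn <- colnames(out)
      if (!is.null(cn) && !is.null(colnames(degCounts))) {
        cn[ri] <- paste0("deg_", colnames(degCounts)[pi_])
        colnames(out) <- make.unique(cn)
      }
    }
    out
  })
}

#' Fold-change perturbation of target cells
#'
#' Multiplies the counts of `nGenes` randomly chosen genes by `fold`
#' (rounded to the nearest integer) in the target cells only.
#'
#' @param counts cells x genes matrix
#' @param targetCells indices of cells to perturb (non-empty)
#' @param nGenes number of genes to perturb
#' @param fold multiplicative factor (default 3)
#' @param seed RNG seed
#' @return perturbed matrix
#' @export
perturbUpregulate <- function(counts, targetCells, nGenes, fold = 3,
                              seed = 1L) {
  if (length(targetCells) == 0) stop("no target cells")
  nGenes <- as.integer(nGenes)
  stopifnot(nGenes >= 0L, nGenes <= ncol(counts))
  .withSeed(seed, {
    genes <- sample.int(ncol(counts), nGenes)
    out <- counts
    out[targetCells, genes] <- round(out[targetCells, genes] * fold)
    out
  })
}

#' Multi-scale count series with a fixed rare-cell count
#'
#' One dataset per scale, each with exactly `rareN` rare cells (group
#' sizes forced, not multinomial) and the remainder in the major group,
#' generated by [simulateCounts()] with the given base parameters.
#'
#' @param scales integer cell counts (each > `rareN`)
#' @param rareN exact rare cells per dataset (default 10)
#' @param seed RNG seed; each scale gets a sub-seed derived from it
#' @param ... base parameters forwarded to [simulateCounts()]
#' @return named list (one element per scale) of [simulateCounts()]
#'   results plus a `scale` field
#' @export
multiscaleSeries <- function(scales, rareN = 10L, seed = 1L, ...) {
  scales <- as.integer(scales)
  if (any(scales <= rareN)) stop("invalid scale: must exceed rareN")
  out <- lapply(seq_along(scales), function(i) {
    sc <- scales[i]
    sub <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    sim <- simulateCounts(batchCells = sc,
                          groupSizes = c(sc - rareN, rareN),
                          seed = sub, ...)
    sim$scale <- sc
    sim
  })
  stats::setNames(out, paste0("n", scales))
}
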