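#' Majority-type annotation of predicted clusters
#'
#' Maps every predicted cluster to the most frequent ground-truth type
#' among its members; modal ties go to the alphabetically first type.
#'
#' @param pred per-cell predicted cluster labels
#' @param truth per-cell true type labels (same cells, same order)
#' @return named character vector cluster -> type
#' @export
annotateClusters <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.character(pred)
  truth <- as.character(truth)
  clusters <- sort(unique(pred))
  ann <- vapply(clusters, function(cl) {
    tt <- table(truth[pred == cl])
    tt <- tt[order(-as.vector(tt), names(tt))]
    names(tt)[1]
  }, character(1))
  stats::setNames(ann, clusters)
}

.positiveSet <- function(pred, truth, rareType) {
  ann <- annotateClusters(pred, truth)
  pos <- names(ann)[ann == rareType]
  which(as.character(pred) %in% pos)
}

#' Precision, recall and F1 for one rare type
#'
#' The positive prediction set is the union of all clusters whose
#' majority-type annotation equals `rareType`; TP/FP/FN come from its
#' overlap with the true member set.  With an empty positive set all three
#' metrics are 0 by convention.
#'
#' @inheritParams annotateClusters
#' @param rareType a type present in `truth`
#' @return named numeric vector (precision, recall, f1)
#' @export
rarePRF <- function(pred, truth, rareType) {
  truth <- as.character(truth)
  if (!rareType %in% truth) stop("type not in truth")
  S <- .positiveSet(pred, truth, rareType)
  T_ <- which(truth == rareType)
  tp <- length(intersect(S, T_))
  fp <- length(setdiff(S, T_))
  fn <- length(setdiff(T_, S))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Jaccard index for one rare type
#'
#' |S intersect T| / |S union T| between the positive prediction set S
#' (union of clusters annotated to `rareType`) and the true member set T.
#'
#' @inheritParams rarePRF
#' @return a single value in `[0, 1]`
#' @export
jaccardIndex <- function(pred, truth, rareType) {
  truth <- as.character(truth)
  if (!rareType %in% truth) stop("type not in truth")
  S <- .positiveSet(pred, truth, rareType)
  T_ <- which(truth == rareType)
  u <- length(union(S, T_))
  if (u == 0) return(0)
  length(intersect(S, T_)) / u
}

#' Normalized mutual information of two labelings
#'
#' Mutual information normalized, by default, by the arithmetic mean of
#' the two entropies.  When either labeling has zero entropy the quotient
#' is undefined; the convention here is 1 when the two labelings induce
#' the same set partition and 0 otherwise.
#'
#' @param pred,truth per-cell labels (same cells, same order)
#' @param variant normalization: "average" (default), "min", "max" or
#'   "sqrt" of the two entropies
#' @return a value in `[0, 1]`
#' @export
nmi <- function(pred, truth, variant = c("average", "min", "max", "sqrt")) {
  variant <- match.arg(variant)
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  a <- as.integer(factor(pred))
  b <- as.integer(factor(truth))
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (ha == 0 || hb == 0) {
    samePartition <- identical(a, as.integer(factor(b)))
    return(if (samePartition) 1 else 0)
  }
  outer_ <- outer(pi_, pj_)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer_), 0))
  denom <- switch(variant,
    average = (ha + hb) / 2,
    min = min(ha, hb),
    max = max(ha, hb),
    sqrt = sqrt(ha * hb))
  max(0, min(1, mi / denom))
}

#' Score a predicted partition against ground truth
#'
#' Annotates clusters by majority type, then reports per-rare-type TP, FP,
#' FN, precision, recall, F1 and Jaccard index plus global NMI.  Rare
#' types default to those below `rareFrac` of all cells (the <1%
#' convention).
#'
#' @inheritParams nmi
#' @param rareTypes explicit rare type list; `NULL` derives it from
#'   `rareFrac`
#' @param rareFrac rarity frequency cutoff (default 0.01)
#' @return an [EvaluationReport-class]
#' @export
evaluateClustering <- function(pred, truth, rareTypes = NULL,
                               rareFrac = 0.01) {
  truth <- as.character(truth)
  if (is.null(rareTypes)) {
    freq <- table(truth) / length(truth)
    rareTypes <- names(freq)[freq < rareFrac]
  }
  rareTypes <- sort(as.character(rareTypes))
  ann <- annotateClusters(pred, truth)
  rows <- lapply(rareTypes, function(tp) {
    S <- .positiveSet(pred, truth, tp)
    T_ <- which(truth == tp)
    prf <- rarePRF(pred, truth, tp)
    data.frame(type = tp,
               tp = length(intersect(S, T_)),
               fp = length(setdiff(S, T_)),
               fn = length(setdiff(T_, S)),
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]],
               jaccard = jaccardIndex(pred, truth, tp))
  })
  perType <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), tp = integer(), fp = integer(),
               fn = integer(), precision = numeric(), recall = numeric(),
               f1 = numeric(), jaccard = numeric())
  new("EvaluationReport", perType = perType, nmi = nmi(pred, truth),
      annotation = ann, rareTypes = rareTypes)
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport: NMI =", round(object@nmi, 4), "\n")
  if (nrow(object@perType)) print(object@perType, row.names = FALSE)
})
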