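#' @import methods
NULL

#' NeighborIndex: directed kNN lists on an embedding
#'
#' Per-cell ordered nearest-neighbor lists, the single source of truth for
#' every edge query in the package.  Row \code{i} of \code{nnIdx} holds the
#' \code{kParam - 1} nearest other cells of cell \code{i} by ascending
#' Euclidean distance (the cell itself is implicitly at rank 0); equal
#' distances are ordered by ascending cell index, so the object is a
#' deterministic function of the embedding and \code{kParam}.
#'
#' @slot cellIds character vector of unique cell identifiers; their order
#'   defines the integer cell index used everywhere else.
#' @slot nnIdx integer matrix, n_cells x min(kParam - 1, n_cells - 1),
#'   1-based neighbor indices.
#' @slot nnDist numeric matrix of matching Euclidean distances,
#'   non-decreasing along each row.
#' @slot kParam integer neighbor-list capacity (default 20), counting the
#'   implicit self at rank 0.
#' @slot approximate logical; TRUE when the lists came from an approximate
#'   search rather than the exact scan.
#'
#' @seealso [buildKnn()], [neighborhood()]
#' @export
setClass("NeighborIndex",
  representation(
    cellIds = "character",
    nnIdx = "matrix",
    nnDist = "matrix",
    kParam = "integer",
    approximate = "logical"
  )
)

setValidity("NeighborIndex", function(object) {
  n <- length(object@cellIds)
  m <- ncol(object@nnIdx)
  msg <- character()
  if (n < 2) msg <- c(msg, "need at least 2 cells")
  if (anyDuplicated(object@cellIds)) msg <- c(msg, "cell ids must be unique")
  if (object@kParam < 2) msg <- c(msg, "kParam must be >= 2")
  if (nrow(object@nnIdx) != n || nrow(object@nnDist) != n)
    msg <- c(msg, "neighbor matrices must have one row per cell")
  if (m != min(object@kParam - 1L, n - 1L))
    msg <- c(msg, "neighbor lists must have min(kParam - 1, n - 1) entries")
  if (!identical(dim(object@nnIdx), dim(object@nnDist)))
    msg <- c(msg, "index and distance matrices must match")
  if (n >= 2 && m >= 1) {
    if (any(object@nnIdx == seq_len(n)))
      msg <- c(msg, "a cell may not list itself as a neighbor")
    if (any(object@nnIdx < 1L) || any(object@nnIdx > n))
      msg <- c(msg, "neighbor indices out of range")
    if (m >= 2 && any(object@nnDist[, -1, drop = FALSE] <
                      object@nnDist[, -m, drop = FALSE]))
      msg <- c(msg, "distances must be non-decreasing along each list")
  }
  if (length(msg)) msg else TRUE
})

#' QScores: per-cell neighborhood connectivity
#'
#' Holds the connectivity score Q of every cell together with the
#' neighborhood size k it was computed at.  Q is the fraction of the k x k
#' directed edges emanating from a cell and its k-1 nearest neighbors
#' (self-edges included) whose targets stay inside that neighborhood; it
#' ranges between 1/k and 1, and is structurally bounded below by
#' (2k-1)/k^2 because the center's k out-edges and every member's self-edge
#' are always internal.
#'
#' @slot q named numeric vector of scores, one per cell.
#' @slot k integer neighborhood size used (default 6).
#' @seealso [allQ()], [cellQ()]
#' @export
setClass("QScores", representation(q = "numeric", k = "integer"))

setValidity("QScores", function(object) {
  k <- object@k
  if (length(k) != 1L || k < 1L) return("k must be a single positive integer")
  if (any(!is.finite(object@q))) return("Q scores must be finite")
  tol <- 1e-12
  if (any(object@q < 1 / k - tol) || any(object@q > 1 + tol))
    return("Q scores must lie in [1/k, 1]")
  TRUE
})

#' ClusterAssignment: per-cell labels and their provenance
#'
#' @slot labels integer vector of cluster labels (one per cell).  During
#'   propagation labels are waypoint cell indices; the final result
#'   relabels clusters 0..(m-1).
#' @slot stage character, one of "propagated", "voted", "merged", "final".
#' @slot waypoints integer indices of waypoint cells (local Q maxima that
#'   kept their own label).
#' @slot iterationsUsed integer, label-update rounds consumed.
#' @slot converged logical, whether a fixed point was reached before the
#'   iteration cap.
#' @export
setClass("ClusterAssignment",
  representation(
    labels = "integer",
    stage = "character",
    waypoints = "integer",
    iterationsUsed = "integer",
    converged = "logical"
  )
)

setValidity("ClusterAssignment", function(object) {
  if (!object@stage %in% c("propagated", "voted", "merged", "final"))
    return("unknown stage")
  if (anyNA(object@labels)) return("every cell must be labeled")
  TRUE
})

#' RareQParams: tuning parameters of the inference engine
#'
#' @slot k integer neighborhood size for Q (default 6; a small value
#'   accommodates extremely rare populations).
#' @slot kParam integer kNN-list capacity (default 20).
#' @slot qThreshold numeric; clusters whose mean member Q strictly exceeds
#'   this are retained as rare populations (default 0.6).
#' @slot ratioThreshold numeric; minimum fraction of a cluster's out-edges
#'   that must point at the merge partner (default 0.2).
#' @slot voteK integer neighborhood size for majority voting (default = k).
#' @slot maxPropagationIters integer safety cap on label propagation.
#' @slot maxVoteRounds integer cap on voting rounds.
#' @slot minClusterSize integer; final non-rare clusters smaller than this
#'   are force-assigned to their most-connected neighbor (default 1 =
#'   strict behavior, no forcing).
#' @seealso [RareQParams()], [runRareQ()]
#' @export
setClass("RareQParams",
  representation(
    k = "integer",
    kParam = "integer",
    qThreshold = "numeric",
    ratioThreshold = "numeric",
    voteK = "integer",
    maxPropagationIters = "integer",
    maxVoteRounds = "integer",
    minClusterSize = "integer"
  )
)

setValidity("RareQParams", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@kParam < 2L) msg <- c(msg, "kParam must be >= 2")
  if (object@voteK < 1L) msg <- c(msg, "voteK must be >= 1")
  if (object@k > object@kParam) msg <- c(msg, "k must not exceed kParam")
  if (object@voteK > object@kParam)
    msg <- c(msg, "voteK must not exceed kParam")
  for (s in c("qThreshold", "ratioThreshold")) {
    v <- slot(object, s)
    if (v <= 0 || v >= 1) msg <- c(msg, paste(s, "must lie in (0, 1)"))
  }
  if (object@maxPropagationIters < 1L || object@maxVoteRounds < 1L ||
      object@minClusterSize < 1L)
    msg <- c(msg, "iteration caps and minClusterSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RareQResult: the full output of a run
#'
#' @slot assignment [ClusterAssignment-class] with final labels
#'   (contiguous integers from 0, largest cluster first).
#' @slot clusterStats data.frame with one row per final cluster: cluster,
#'   n, kParamEff, meanQ, qC, isRare.
#' @slot rareClusterIds integer ids of retained rare clusters.
#' @slot qScores [QScores-class] used for the run.
#' @slot params [RareQParams-class] used for the run.
#' @seealso [runRareQ()]
#' @export
setClass("RareQResult",
  representation(
    assignment = "ClusterAssignment",
    clusterStats = "data.frame",
    rareClusterIds = "integer",
    qScores = "QScores",
    params = "RareQParams"
  )
)

setValidity("RareQResult", function(object) {
  st <- object@clusterStats
  if (!all(object@rareClusterIds %in% st$cluster))
    return("rare cluster ids must appear in clusterStats")
  if (!setequal(unique(object@assignment@labels), st$cluster))
    return("clusterStats must cover exactly the assigned clusters")
  TRUE
})

#' EvaluationReport: predicted partition scored against ground truth
#'
#' @slot perType data.frame with one row per rare type: type, tp, fp, fn,
#'   precision, recall, f1, jaccard.
#' @slot nmi numeric normalized mutual information of the two labelings.
#' @slot annotation named character, majority-type annotation of each
#'   predicted cluster.
#' @slot rareTypes character, the rare types evaluated.
#' @seealso [evaluateClustering()]
#' @export
setClass("EvaluationReport",
  representation(
    perType = "data.frame",
    nmi = "numeric",
    annotation = "character",
    rareTypes = "character"
  )
)
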