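#' Construct the parameter set for the inference engine
#'
#' @param k neighborhood size for Q scoring and (by default) voting;
#'   default 6, small enough to resolve extremely rare populations.
#' @param kParam kNN-list capacity, default 20.
#' @param qThreshold retention threshold on cluster mean Q, default 0.6.
#' @param ratioThreshold minimum out-edge fraction toward the merge
#'   partner, default 0.2.
#' @param voteK voting neighborhood size; `NULL` (default) means `k`.
#' @param maxPropagationIters safety cap on propagation rounds, default 100.
#' @param maxVoteRounds cap on voting rounds, default 10.
#' @param minClusterSize minimum final cluster size, default 1 (strict
#'   behavior: singleton clusters are left alone).
#' @return a [RareQParams-class]
#' @export
RareQParams <- function(k = 6L, kParam = 20L, qThreshold = 0.6,
                        ratioThreshold = 0.2, voteK = NULL,
                        maxPropagationIters = 100L, maxVoteRounds = 10L,
                        minClusterSize = 1L) {
  if (is.null(voteK)) voteK <- k
  new("RareQParams", k = as.integer(k), kParam = as.integer(kParam),
      qThreshold = qThreshold, ratioThreshold = ratioThreshold,
      voteK = as.integer(voteK),
      maxPropagationIters = as.integer(maxPropagationIters),
      maxVoteRounds = as.integer(maxVoteRounds),
      minClusterSize = as.integer(minClusterSize))
}

#' Q-guided label propagation
#'
#' Every cell starts as its own cluster.  A cell adopts the label of the
#' neighbor in its size-k neighborhood with the highest Q, provided that Q
#' strictly exceeds its own (ties among equal-highest neighbors go to the
#' smallest cell index); cells with no strictly better neighbor are
#' waypoints and keep their own label.  Iterating the adoption to its fixed
#' point gives every cell the label of the waypoint reached by following
#' best-neighbor pointers.  Because the pointer always increases Q strictly
#' there are no cycles and the fixed point exists; it is resolved here by
#' pointer doubling, with `maxPropagationIters` as a safety cap.
#'
#' @param index a [NeighborIndex-class]
#' @param q a [QScores-class] computed on `index` with `k = params@k`
#' @param params a [RareQParams-class]
#' @return a [ClusterAssignment-class], stage "propagated"; labels are
#'   waypoint cell indices
#' @export
propagateLabels <- function(index, q, params = RareQParams()) {
  n <- length(index@cellIds)
  qv <- qValues(q)
  if (length(qv) != n) stop("inconsistent inputs: index and q sizes differ")
  k <- params@k
  if (neighborhoodSize(q) != k)
    stop("inconsistent inputs: q computed at a different k")
  parent <- seq_len(n)
  if (k >= 2L) {
    nb <- index@nnIdx[, seq_len(k - 1L), drop = FALSE]
    qn <- matrix(qv[nb], n, k - 1L)
    best <- do.call(pmax, as.data.frame(qn))
    # among neighbors attaining the best Q, take the smallest cell index
    cand <- nb
    cand[qn < best] <- NA_integer_
    bestNbr <- do.call(pmin, c(as.data.frame(cand), na.rm = TRUE))
    adopt <- best > qv
    parent[adopt] <- bestNbr[adopt]
  }
  # pointer doubling to the fixed point labels(i) = labels(parent(i))
  lab <- parent
  iters <- 0L
  converged <- FALSE
  while (iters < params@maxPropagationIters) {
    iters <- iters + 1L
    nxt <- lab[lab]
    if (identical(nxt, lab)) { converged <- TRUE; break }
    lab <- nxt
  }
  new("ClusterAssignment", labels = lab, stage = "propagated",
      waypoints = which(parent == seq_len(n)), iterationsUsed = iters,
      converged = converged)
}

#' kNN majority-vote refinement
#'
#' Synchronous rounds in which each cell takes the modal label over itself
#' and its `voteK - 1` nearest neighbors; a tie for the mode keeps the
#' current label.  Stops at the first round with no change, or after
#' `maxVoteRounds`.
#'
#' @inheritParams propagateLabels
#' @param assignment a propagated [ClusterAssignment-class]
#' @return a [ClusterAssignment-class], stage "voted"
#' @export
voteRefine <- function(index, assignment, params = RareQParams()) {
  n <- length(index@cellIds)
  lab <- assignment@labels
  if (length(lab) != n) stop("inconsistent inputs")
  vk <- min(params@voteK, n)
  rounds <- 0L
  if (vk >= 2L) {
    while (rounds < params@maxVoteRounds) {
      rounds <- rounds + 1L
      nxt <- .vote_round_cpp(index@nnIdx, lab, vk)
      if (identical(nxt, lab)) break
      lab <- nxt
    }
  }
  new("ClusterAssignment", labels = lab, stage = "voted",
      waypoints = assignment@waypoints,
      iterationsUsed = assignment@iterationsUsed + rounds,
      converged = assignment@converged)
}

#' Retain high-connectivity clusters as rare populations
#'
#' Clusters whose mean member Q strictly exceeds `qThreshold` are frozen as
#' rare populations: they take no further part in merging, neither as
#' source nor as target.
#'
#' @param stats data.frame from [computeClusterStats()]
#' @param qThreshold retention threshold (default 0.6)
#' @return integer vector of retained cluster ids
#' @export
retainRare <- function(stats, qThreshold = 0.6) {
  if (is.null(stats) || nrow(stats) == 0L) return(integer())
  as.integer(stats$cluster[stats$meanQ > qThreshold])
}

# directed out-edge counts from cluster members to every label, full
# capacity kParam - 1, self-loops excluded by construction
.outEdgeCounts <- function(index, labels, members) {
  targets <- labels[as.vector(index@nnIdx[members, , drop = FALSE])]
  counts <- table(targets)
  stats::setNames(as.vector(counts), names(counts))
}

#' Recursive Qc-guided cluster merging
#'
#' Visits non-rare clusters in ascending size (ties by smaller id) in
#' repeated full passes until a pass performs no merge.  For each cluster C
#' the candidate partner Cn is the non-rare cluster receiving the most
#' directed out-edges from C's members (full capacity `kParam`, self-loops
#' excluded; ties toward the smaller id).  The merge is accepted iff the
#' union's Qc strictly exceeds both parts' Qc and the fraction of C's
#' out-edge budget `|C| * (kParam - 1)` pointing at Cn exceeds
#' `ratioThreshold`.  The merged cluster takes the id of the larger
#' constituent (ties toward the smaller id).  Retained rare clusters are
#' untouchable.  With `minClusterSize > 1`, surviving non-rare clusters
#' below that size are afterwards force-assigned to the non-rare cluster
#' receiving most of their edges, without the Qc conditions.
#'
#' @inheritParams propagateLabels
#' @param assignment a voted [ClusterAssignment-class]
#' @param rareIds integer ids of retained rare clusters
#' @return a [ClusterAssignment-class], stage "merged"
#' @export
mergeClusters <- function(index, assignment, rareIds = integer(),
                          params = RareQParams()) {
  lab <- assignment@labels
  if (length(rareIds) && !all(rareIds %in% lab))
    stop("invalid rare set: unknown cluster id")
  rareIds <- as.integer(rareIds)
  kp <- index@kParam
  m <- ncol(index@nnIdx)

  repeat {
    sizes <- table(lab)
    ids <- as.integer(names(sizes))
    ord <- ids[order(as.vector(sizes), ids)]
    ord <- setdiff(ord, rareIds)
    mergedAny <- FALSE
    for (C in ord) {
      mem <- which(lab == C)
      if (!length(mem)) next # merged away earlier in this pass
      counts <- .outEdgeCounts(index, lab, mem)
      counts <- counts[!(names(counts) %in% as.character(c(C, rareIds)))]
      counts <- counts[counts > 0]
      if (!length(counts)) next
      topIds <- as.integer(names(counts)[counts == max(counts)])
      Cn <- min(topIds)
      ratio <- max(counts) / (length(mem) * (kp - 1L))
      if (ratio <= params@ratioThreshold) next
      memN <- which(lab == Cn)
      qcC <- clusterQ(index, mem)
      qcN <- clusterQ(index, memN)
      qcU <- clusterQ(index, c(mem, memN))
      if (qcU > qcC && qcU > qcN) {
        newId <- if (length(mem) > length(memN)) C
                 else if (length(memN) > length(mem)) Cn
                 else min(C, Cn)
        lab[c(mem, memN)] <- newId
        mergedAny <- TRUE
      }
    }
    if (!mergedAny) break
  }

  if (params@minClusterSize > 1L) {
    repeat {
      sizes <- table(lab)
      ids <- as.integer(names(sizes))
      small <- setdiff(ids[as.vector(sizes) < params@minClusterSize], rareIds)
      if (!length(small)) break
      C <- small[order(as.vector(sizes)[match(small, ids)], small)][1]
      mem <- which(lab == C)
      counts <- .outEdgeCounts(index, lab, mem)
      counts <- counts[!(names(counts) %in% as.character(c(C, rareIds)))]
      counts <- counts[counts > 0]
      if (!length(counts)) break # isolated; nothing to assign to
      topIds <- as.integer(names(counts)[counts == max(counts)])
      lab[mem] <- min(topIds)
    }
  }

  new("ClusterAssignment", labels = lab, stage = "merged",
      waypoints = assignment@waypoints,
      iterationsUsed = assignment@iterationsUsed,
      converged = assignment@converged)
}

#' Run the full rare-population inference pipeline
#'
#' Builds the kNN index (when given an embedding), scores Q, propagates
#' labels from waypoints, refines by kNN voting, retains clusters with mean
#' Q above the threshold as rare populations, and recursively merges the
#' remaining clusters into major populations.  The core contains no
#' randomness: two runs on identical input give identical output.  Final
#' cluster ids are contiguous integers from 0, ordered by decreasing size
#' (ties by smallest member index).
#'
#' @param input a numeric embedding matrix (cells x dims, rownames = cell
#'   ids) or a prebuilt [NeighborIndex-class]
#' @param params a [RareQParams-class]
#' @param exactThreshold passed to [buildKnn()] when `input` is an
#'   embedding
#' @return a [RareQResult-class]
#' @examples
#' sim <- makeBlobs(nCells = 300, proportions = c(major = 0.95, rare = 0.05),
#'                  separation = 10, dim = 5, seed = 1)
#' res <- runRareQ(sim$embedding)
#' clusterStats(res)
#' @export
runRareQ <- function(input, params = RareQParams(), exactThreshold = 50000L) {
  index <- if (is(input, "NeighborIndex")) input
           else buildKnn(input, kParam = params@kParam,
                         exactThreshold = exactThreshold)
  n <- length(index@cellIds)
  if (n < params@k) stop("insufficient cells: fewer cells than k")
  if (params@k > index@kParam) stop("k exceeds index capacity")
  q <- allQ(index, k = params@k)
  asg <- propagateLabels(index, q, params)
  asg <- voteRefine(index, asg, params)
  stats <- computeClusterStats(index, asg@labels, q)
  rare <- retainRare(stats, params@qThreshold)
  asg <- mergeClusters(index, asg, rare, params)

  # contiguous final ids from 0, largest cluster first
  lab <- asg@labels
  sizes <- table(lab)
  ids <- as.integer(names(sizes))
  firstMember <- vapply(ids, function(cl) which(lab == cl)[1], integer(1))
  ord <- ids[order(-as.vector(sizes), firstMember)]
  newId <- stats::setNames(seq_along(ord) - 1L, ord)
  finalLab <- as.integer(newId[as.character(lab)])
  finalRare <- as.integer(newId[as.character(rare)])

  finalAsg <- new("ClusterAssignment", labels = finalLab, stage = "final",
                  waypoints = asg@waypoints,
                  iterationsUsed = asg@iterationsUsed,
                  converged = asg@converged)
  finalStats <- computeClusterStats(index, finalLab, q)
  finalStats$isRare <- finalStats$cluster %in% finalRare
  new("RareQResult", assignment = finalAsg, clusterStats = finalStats,
      rareClusterIds = sort(finalRare), qScores = q, params = params)
}

#' @rdname ClusterAssignment-class
#' @param x a [ClusterAssignment-class] or [RareQResult-class]
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname ClusterAssignment-class
#' @export
setMethod("waypoints", "ClusterAssignment", function(x) x@waypoints)

#' @rdname RareQResult-class
#' @param x,object a [RareQResult-class]
#' @export
setMethod("clusterLabels", "RareQResult",
          function(x) x@assignment@labels)

#' @rdname RareQResult-class
#' @export
setMethod("clusterStats", "RareQResult", function(x) x@clusterStats)

#' @rdname RareQResult-class
#' @export
setMethod("rareClusterIds", "RareQResult", function(x) x@rareClusterIds)

#' @rdname RareQResult-class
#' @export
setMethod("qValues", "RareQResult", function(x) qValues(x@qScores))

#' @rdname RareQResult-class
#' @export
setMethod("isRareCell", "RareQResult",
          function(x) x@assignment@labels %in% x@rareClusterIds)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@labels), "cells,",
      length(unique(object@labels)), "clusters, stage =", object@stage, "\n")
})

setMethod("show", "RareQResult", function(object) {
  st <- object@clusterStats
  cat("RareQResult:", length(object@assignment@labels), "cells,",
      nrow(st), "clusters (", length(object@rareClusterIds), "rare )\n")
  print(utils::head(st, 10))
})

setMethod("show", "RareQParams", function(object) {
  cat(sprintf(
    "RareQParams: k=%d kParam=%d qThreshold=%.2f ratioThreshold=%.2f voteK=%d\n",
    object@k, object@kParam, object@qThreshold, object@ratioThreshold,
    object@voteK))
})
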