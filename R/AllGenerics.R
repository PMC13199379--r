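#' @rdname NeighborIndex-class
#' @param object,x a [NeighborIndex-class]
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname NeighborIndex-class
#' @export
setGeneric("kParam", function(x) standardGeneric("kParam"))

#' @rdname NeighborIndex-class
#' @export
setGeneric("neighborMatrix", function(x) standardGeneric("neighborMatrix"))

#' @rdname NeighborIndex-class
#' @export
setGeneric("neighborDistances",
           function(x) standardGeneric("neighborDistances"))

#' @rdname NeighborIndex-class
#' @export
setGeneric("isApproximate", function(x) standardGeneric("isApproximate"))

#' @rdname QScores-class
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname QScores-class
#' @export
setGeneric("neighborhoodSize", function(x) standardGeneric("neighborhoodSize"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("waypoints", function(x) standardGeneric("waypoints"))

#' @rdname RareQResult-class
#' @export
setGeneric("clusterStats", function(x) standardGeneric("clusterStats"))

#' @rdname RareQResult-class
#' @export
setGeneric("rareClusterIds", function(x) standardGeneric("rareClusterIds"))

#' @rdname RareQResult-class
#' @export
setGeneric("isRareCell", function(x) standardGeneric("isRareCell"))
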