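#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname accessors
#' @export
setGeneric("unmatchedClusters", function(x) standardGeneric("unmatchedClusters"))

#' @rdname accessors
#' @export
setGeneric("centroidMeans", function(x) standardGeneric("centroidMeans"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("familyAssignments", function(x) standardGeneric("familyAssignments"))

#' @rdname accessors
#' @export
setGeneric("discardedClusters", function(x) standardGeneric("discardedClusters"))

#' @rdname accessors
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))

#' @rdname accessors
#' @export
setGeneric("mergedSet", function(x) standardGeneric("mergedSet"))

#' @rdname accessors
#' @export
setGeneric("correlationMaps", function(x) standardGeneric("correlationMaps"))

#' @rdname accessors
#' @export
setGeneric("contributionTable", function(x) standardGeneric("contributionTable"))
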