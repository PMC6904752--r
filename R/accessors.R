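#' Accessors for consolidation objects
#'
#' Small accessor functions so user code never touches slots directly:
#' `corMatrix()` the Spearman matrix of a [CorrelationMap-class];
#' `matchedPairs()` its one-to-one matching; `unmatchedClusters()` the
#' clusters without a reciprocal partner; `centroidMeans()` /
#' `clusterSizes()` the profile matrix and sizes of a [CentroidSet-class];
#' `familyAssignments()` / `discardedClusters()` / `familyNames()` the
#' content of a [FamilyMap-class]; `mergedSet()`, `correlationMaps()`,
#' `contributionTable()` the parts of a [ConsolidationResult-class].
#'
#' @param x the object.
#' @return the requested component (a matrix, data.frame, DataFrame,
#'   character vector or SingleCellExperiment).
#' @name accessors
#' @aliases corMatrix matchedPairs unmatchedClusters centroidMeans
#'   clusterSizes familyAssignments discardedClusters familyNames mergedSet
#'   correlationMaps contributionTable
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("0", "1"), c("g1", "g2", "g3")))
#' a <- newCentroidSet(m, sizes = c(5L, 7L), unit = "d0.r1", day = 0L, replicate = "r1")
#' clusterSizes(a)
NULL

#' @rdname accessors
setMethod("corMatrix", "CorrelationMap", function(x) x@rho)

#' @rdname accessors
setMethod("matchedPairs", "CorrelationMap", function(x) x@matching)

#' @rdname accessors
setMethod("unmatchedClusters", "CorrelationMap",
    function(x) list(a = x@unmatchedA, b = x@unmatchedB))

#' @rdname accessors
setMethod("centroidMeans", "CentroidSet", function(x) x@means)

#' @rdname accessors
setMethod("clusterSizes", "CentroidSet",
    function(x) stats::setNames(x@sizes, rownames(x@means)))

#' @rdname accessors
setMethod("familyAssignments", "FamilyMap", function(x) x@assignments)

#' @rdname accessors
setMethod("discardedClusters", "FamilyMap", function(x) x@discarded)

#' @rdname accessors
setMethod("familyNames", "FamilyMap",
    function(x) sort(unique(as.character(x@assignments$family))))

#' @rdname accessors
setMethod("familyAssignments", "ConsolidationResult",
    function(x) familyAssignments(x@familyMap))

#' @rdname accessors
setMethod("discardedClusters", "ConsolidationResult",
    function(x) discardedClusters(x@familyMap))

#' @rdname accessors
setMethod("familyNames", "ConsolidationResult",
    function(x) familyNames(x@familyMap))

#' @rdname accessors
setMethod("mergedSet", "ConsolidationResult", function(x) x@merged)

#' @rdname accessors
setMethod("correlationMaps", "ConsolidationResult", function(x) x@maps)

#' @rdname accessors
setMethod("contributionTable", "ConsolidationResult",
    function(x) x@contribution)

setMethod("show", "CentroidSet", function(object) {
    cat(sprintf("CentroidSet of unit %s (day %d, replicate %s): %d clusters x %d genes\n",
        object@unit, object@day, object@replicate,
        nrow(object@means), ncol(object@means)))
    cat("cluster sizes:", paste(object@sizes, collapse = ", "), "\n")
})

setMethod("show", "CorrelationMap", function(object) {
    cat(sprintf("CorrelationMap %s (day %d) vs %s (day %d): %d x %d\n",
        object@unitA, object@dayA, object@unitB, object@dayB,
        nrow(object@rho), ncol(object@rho)))
    if (nrow(object@matching))
        cat(sprintf("  %d matched pairs, %d + %d unmatched\n",
            nrow(object@matching),
            length(object@unmatchedA), length(object@unmatchedB)))
    else cat("  (no matching computed)\n")
})

setMethod("show", "FamilyMap", function(object) {
    fam <- table(as.character(object@assignments$family))
    cat(sprintf("FamilyMap: %d retained provisional clusters in %d families; %d discarded\n",
        nrow(object@assignments), length(fam), nrow(object@discarded)))
    if (length(fam))
        cat("  clusters per family:",
            paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
})

setMethod("show", "ConsolidationResult", function(object) {
    cat(sprintf("ConsolidationResult: %d units, %d correlation maps\n",
        nrow(object@units), length(object@maps)))
    show(object@familyMap)
    if (!is.null(object@merged))
        cat(sprintf("  merged set: %d genes x %d cells, %d final clusters\n",
            nrow(object@merged), ncol(object@merged),
            length(unique(object@merged$final_cluster))))
})

#' Construct a CentroidSet
#'
#' @param means clusters x genes numeric matrix with dimnames.
#' @param sizes integer vector of cluster sizes.
#' @param unit,day,replicate unit metadata.
#' @return a [CentroidSet-class].
#' @export
newCentroidSet <- function(means, sizes, unit = "unit", day = 0L,
                           replicate = "r1") {
    new("CentroidSet", means = means, sizes = as.integer(sizes),
        unit = as.character(unit), day = as.integer(day),
        replicate = as.character(replicate))
}
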