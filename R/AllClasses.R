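#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CentroidSet: per-cluster mean expression profiles
#'
#' Holds the clusters x genes matrix of mean log-normalized expression for
#' the provisional clusters of one replicate at one timepoint, together with
#' cluster sizes. Two CentroidSets can be rank-correlated only if they carry
#' an identical, identically ordered gene set.
#'
#' @slot means numeric matrix, clusters x genes; rownames are cluster labels,
#'   colnames the shared gene set.
#' @slot sizes integer vector of cells per cluster, parallel to rows.
#' @slot unit character(1), an identifier of the (day, replicate) unit.
#' @slot day integer(1) day of the timecourse.
#' @slot replicate character(1) replicate id.
#'
#' @exportClass CentroidSet
setClass("CentroidSet",
    representation(means = "matrix", sizes = "integer",
                   unit = "character", day = "integer",
                   replicate = "character"))

setValidity("CentroidSet", function(object) {
    msg <- NULL
    if (nrow(object@means) != length(object@sizes))
        msg <- c(msg, "length(sizes) must equal nrow(means)")
    if (any(object@sizes < 1L))
        msg <- c(msg, "all cluster sizes must be positive")
    if (is.null(colnames(object@means)))
        msg <- c(msg, "means must carry gene names as colnames")
    if (is.null(msg)) TRUE else msg
})

#' CorrelationMap: rank correlations between two centroid sets
#'
#' The Spearman correlation matrix between every cluster centroid of unit A
#' and every centroid of unit B, plus (once computed) the reciprocal-best
#' matching and the clusters left unmatched on either side.
#'
#' @slot rho numeric matrix, clusters_A x clusters_B, entries in [-1, 1]
#'   (NA where a centroid had zero variance).
#' @slot unitA,unitB character(1) identifiers of the compared units.
#' @slot dayA,dayB integer(1) days of the compared units.
#' @slot matching data.frame with columns `a`, `b`, `rho`: the one-to-one
#'   matched pairs. Empty until [matchAndDiscard()] fills it.
#' @slot unmatchedA,unmatchedB character vectors of cluster labels without a
#'   reciprocal match.
#'
#' @exportClass CorrelationMap
setClass("CorrelationMap",
    representation(rho = "matrix",
                   unitA = "character", unitB = "character",
                   dayA = "integer", dayB = "integer",
                   matching = "data.frame",
                   unmatchedA = "character", unmatchedB = "character"))

setValidity("CorrelationMap", function(object) {
    msg <- NULL
    r <- object@rho
    if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    m <- object@matching
    if (nrow(m)) {
        if (!all(c("a", "b", "rho") %in% names(m)))
            msg <- c(msg, "matching needs columns a, b, rho")
        else if (anyDuplicated(m$a) || anyDuplicated(m$b))
            msg <- c(msg, "matching must be one-to-one")
    }
    if (is.null(msg)) TRUE else msg
})

#' FamilyMap: consolidated family assignment of provisional clusters
#'
#' Maps every retained provisional cluster (one per replicate, day and
#' cluster label) to a consolidated cell-family label ("A", "B", ...,
#' largest family first by total cell count), and records the provisional
#' clusters discarded for failing to align across replicates.
#'
#' @slot assignments DataFrame with columns `unit`, `day`, `replicate`,
#'   `cluster`, `family`, `n_cells`.
#' @slot discarded DataFrame with columns `unit`, `day`, `replicate`,
#'   `cluster`, `n_cells`.
#'
#' @exportClass FamilyMap
setClass("FamilyMap",
    representation(assignments = "DataFrame", discarded = "DataFrame"))

setValidity("FamilyMap", function(object) {
    msg <- NULL
    a <- object@assignments
    need <- c("unit", "cluster", "family")
    if (!all(need %in% colnames(a)))
        msg <- c(msg, "assignments need columns unit, cluster, family")
    else {
        keyA <- paste(a$unit, a$cluster)
        if (anyDuplicated(keyA))
            msg <- c(msg, "a provisional cluster may map to only one family")
        d <- object@discarded
        if (nrow(d) && length(intersect(paste(d$unit, d$cluster), keyA)))
            msg <- c(msg, "discarded and retained clusters must be disjoint")
    }
    if (is.null(msg)) TRUE else msg
})

#' ConsolidationResult: full output of the consolidation pipeline
#'
#' @slot units DataFrame describing the (day, replicate) units analysed.
#' @slot maps list of [CorrelationMap-class] objects, one per compared pair
#'   of units, named "unitA|unitB".
#' @slot familyMap [FamilyMap-class] for the provisional clusters.
#' @slot merged a [SingleCellExperiment::SingleCellExperiment] of the pooled
#'   retained cells with assays `logcounts` and `corrected`, and colData
#'   `barcode`, `unit`, `day`, `replicate`, `batch`, `provisional_cluster`,
#'   `family` (from the provisional consolidation), `final_cluster` and
#'   `final_family` (from the supplemental clustering of the merged set).
#' @slot contribution integer matrix, final clusters x units: how many cells
#'   each unit contributes to each final cluster.
#' @slot params list of the parameters the pipeline ran with.
#'
#' @exportClass ConsolidationResult
setClass("ConsolidationResult",
    representation(units = "DataFrame", maps = "list",
                   familyMap = "FamilyMap", merged = "ANY",
                   contribution = "matrix", params = "list"))

setValidity("ConsolidationResult", function(object) {
    msg <- NULL
    if (length(object@maps) &&
        !all(vapply(object@maps, is, logical(1), "CorrelationMap")))
        msg <- c(msg, "maps must all be CorrelationMap objects")
    if (is.null(msg)) TRUE else msg
})
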