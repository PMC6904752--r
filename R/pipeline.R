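#' Consolidate a timecourse of replicate count matrices into cell families
#'
#' The full consolidation pipeline: per-unit quality control and log
#' normalization; PCA embedding and provisional unsupervised clustering of
#' every (day, replicate) unit; centroid rank-correlation maps for every
#' pair of units (within and between timepoints) over a shared
#' highly-variable gene set; reciprocal-best matching with discard of
#' provisional clusters that fail to align within their timepoint; family
#' consolidation as connected components of the match graph; pooling of
#' retained cells with per-gene batch-mean centering; and a supplemental
#' clustering of the merged set with family assignment by plurality and a
#' per-unit contribution table.
#'
#' @param matrices named list of [SingleCellExperiment::SingleCellExperiment]
#'   objects with a `counts` assay and colData `day` and `replicate`
#'   (e.g. `simulateTimecourse()$matrices`, or [readTenx()] outputs).
#' @param k provisional clusters per unit: a single integer, or a vector
#'   named by unit id for per-unit counts.
#' @param min_rho minimum rank correlation for a valid match.
#' @param qc a [qcParams()], or `NULL` to skip filtering.
#' @param scale_factor normalization scale factor.
#' @param n_hvg highly variable genes for embedding and centroids.
#' @param n_components principal components for clustering.
#' @param method clustering backend, `"kmeans"` or `"graph"`.
#' @param resolution Louvain resolution when `method = "graph"`.
#' @param discard_fraction see [matchAndDiscard()].
#' @param match_method see [matchAndDiscard()].
#' @param nstart k-means restarts (kept high so replicate clusterings land
#'   in consistent optima).
#' @param final_k clusters for the supplemental clustering of the merged
#'   set; default: the number of consolidated families.
#' @param merge if FALSE, stop after matching/discard/family consolidation
#'   (no pooled set, no supplemental clustering) — the alignment-only
#'   analysis used for stability studies over many seeds.
#' @param seed RNG seed for the clustering backends.
#' @return a [ConsolidationResult-class].
#' @examples
#' sim <- simulateTimecourse(simConfig(
#'     timepoints = c(0L, 3L), cells_per_replicate = 120, seed = 2))
#' res <- consolidateTimecourse(sim$matrices, k = 7, seed = 2)
#' familyNames(res)
#' @export
consolidateTimecourse <- function(matrices, k = 7L, min_rho = 0.5,
                                  qc = qcParams(), scale_factor = 10000,
                                  n_hvg = 2000L, n_components = 10L,
                                  method = c("kmeans", "graph"),
                                  resolution = 1, discard_fraction = 1,
                                  match_method = "reciprocal",
                                  final_k = NULL, merge = TRUE, seed = 0L,
                                  nstart = 50L) {
    method <- match.arg(method)
    if (is.null(names(matrices)))
        names(matrices) <- vapply(matrices, function(s)
            unitId(s$day[1], s$replicate[1]), character(1))
    units <- DataFrame(
        unit = names(matrices),
        day = vapply(matrices, function(s) as.integer(s$day[1]), integer(1)),
        replicate = vapply(matrices, function(s)
            as.character(s$replicate[1]), character(1)))

    # per-unit QC + normalization
    norm <- lapply(matrices, function(s) {
        if (!is.null(qc)) s <- applyQC(s, qc)
        normalizeLog(s, scale_factor)
    })

    # shared gene set and HVGs from the pooled log values
    genes <- Reduce(intersect, lapply(norm, rownames))
    if (!length(genes)) stopf("no shared genes across units after QC")
    pooled_lc <- do.call(cbind, lapply(norm, function(s)
        SummarizedExperiment::assay(s, "logcounts")[genes, , drop = FALSE]))
    hvg <- selectHVG(pooled_lc, min(n_hvg, length(genes)))

    # provisional clustering per unit + centroids on the shared HVGs
    k_of <- function(u) if (length(k) == 1L) as.integer(k)
        else as.integer(k[[u]])
    clusterings <- list()
    centroids <- list()
    for (u in names(norm)) {
        s <- norm[[u]]
        emb <- embedPCA(s, n_hvg = n_hvg, n_components = n_components,
                        hvg = intersect(hvg, rownames(s)))
        cl <- clusterCells(emb, k = k_of(u), method = method,
                           resolution = resolution, seed = seed,
                           nstart = nstart)
        clusterings[[u]] <- cl
        centroids[[u]] <- computeCentroids(
            SummarizedExperiment::assay(s, "logcounts"), cl$labels,
            genes = hvg, unit = u, day = units$day[units$unit == u],
            replicate = units$replicate[units$unit == u])
    }

    # correlation maps for every pair of units
    maps <- list()
    un <- names(norm)
    for (i in seq_along(un)) for (j in seq_along(un)) {
        if (j <= i) next
        m <- centroidRankCorrelation(centroids[[un[i]]], centroids[[un[j]]])
        maps[[paste(un[i], un[j], sep = "|")]] <- m
    }

    sizes <- lapply(centroids, clusterSizes)
    mres <- matchAndDiscard(maps, min_rho = min_rho,
                            discard_fraction = discard_fraction,
                            method = match_method)
    fmap <- consolidateFamilies(mres, sizes = sizes)

    params <- list(k = k, min_rho = min_rho, n_hvg = n_hvg,
                   n_components = n_components, method = method,
                   resolution = resolution, seed = seed,
                   discard_fraction = discard_fraction, hvg = hvg,
                   provisional = lapply(clusterings, `[[`, "labels"))
    if (!merge)
        return(new("ConsolidationResult", units = units, maps = mres$maps,
                   familyMap = fmap, merged = NULL,
                   contribution = matrix(integer(), 0, 0), params = params))

    # pool retained cells, correct batch, supplemental clustering
    asg <- familyAssignments(fmap)
    fam_key <- stats::setNames(as.character(asg$family),
                               paste(asg$unit, asg$cluster, sep = "#"))
    kept <- list()
    for (u in names(norm)) {
        labs <- clusterings[[u]]$labels
        key <- paste(u, labs, sep = "#")
        keep <- key %in% names(fam_key)
        if (!any(keep)) next
        s <- norm[[u]][, keep]
        if ("family" %in% colnames(SummarizedExperiment::colData(s)))
            s$family_truth <- s$family    # keep any pre-existing labels
        s$provisional_cluster <- labs[keep]
        s$family <- unname(fam_key[key[keep]])
        s$unit <- u
        kept[[u]] <- s
    }
    if (!length(kept)) stopf("no clusters retained at min_rho = %g", min_rho)
    merged <- poolAndCorrect(kept, batch = names(kept))
    if (is.null(final_k)) final_k <- length(familyNames(fmap))
    fin <- finalCluster(merged, k = final_k, n_hvg = n_hvg,
                        n_components = n_components, seed = seed,
                        method = method, nstart = nstart)
    merged$final_cluster <- fin$labels
    merged$final_family <- fin$family

    params$final_k <- final_k
    new("ConsolidationResult", units = units, maps = mres$maps,
        familyMap = fmap, merged = merged, contribution = fin$contribution,
        params = params)
}

#' Export a ConsolidationResult as TSV tables
#'
#' Writes per-comparison correlation matrices (`cor_<A>_<B>.tsv`), the
#' matching and discard log (`matching.tsv`, `discarded.tsv`), the family
#' map (`family_map.tsv`), the merged clustering (`merged_clusters.tsv`)
#' and the contribution table (`contribution.tsv`).
#'
#' @param result a [ConsolidationResult-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
exportConsolidation <- function(result, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wt <- function(x, f, rn = FALSE)
        utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                           row.names = rn, col.names = TRUE)
    match_rows <- list()
    for (nm in names(result@maps)) {
        m <- result@maps[[nm]]
        wt(corMatrix(m), sprintf("cor_%s_%s.tsv", m@unitA, m@unitB),
           rn = TRUE)
        p <- matchedPairs(m)
        if (nrow(p))
            match_rows[[nm]] <- cbind(unit_a = m@unitA, unit_b = m@unitB, p)
    }
    wt(do.call(rbind, match_rows), "matching.tsv")
    wt(as.data.frame(familyAssignments(result)), "family_map.tsv")
    wt(as.data.frame(discardedClusters(result)), "discarded.tsv")
    merged <- mergedSet(result)
    wt(data.frame(barcode = colnames(merged), unit = merged$unit,
                  provisional_cluster = merged$provisional_cluster,
                  family = merged$family,
                  final_cluster = merged$final_cluster,
                  final_family = merged$final_family),
       "merged_clusters.tsv")
    wt(contributionTable(result), "contribution.tsv", rn = TRUE)
    invisible(dir)
}
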