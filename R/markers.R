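#' Cluster-vs-rest marker statistics with FDR adjustment
#'
#' For every gene and every cluster: the linear-scale fold change of mean
#' back-transformed expression in the cluster over the rest (with a
#' pseudocount guarding zero denominators), a two-sided Wilcoxon rank-sum
#' p-value on the log values (normal approximation with tie and continuity
#' corrections, matching `stats::wilcox.test`), and Benjamini-Hochberg
#' adjustment across genes within each cluster comparison. A t-test
#' alternative is config-switchable. Adjusted p-values are floored at
#' 1e-300 rather than reported as 0.
#'
#' @param x genes x cells matrix of log-normalized values, or an object
#'   with a `logcounts` assay.
#' @param clusters cluster/family label per cell.
#' @param test `"wilcox"` (default) or `"t"`.
#' @param eps pseudocount on the ratio scale.
#' @return data.frame with columns `gene`, `cluster`, `fold_change`
#'   (ratio scale), `p_value`, `adjusted_p`, `direction` ("up"/"down").
#' @export
differentialMarkers <- function(x, clusters, test = c("wilcox", "t"),
                                eps = 1e-9) {
    test <- match.arg(test)
    lc <- if (is.matrix(x)) x else SummarizedExperiment::assay(x, "logcounts")
    clusters <- as.character(clusters)
    if (length(clusters) != ncol(lc))
        stopf("one cluster label per cell required")
    labs <- sort(unique(clusters))
    if (length(labs) < 2) stopf("at least 2 clusters required")
    if (any(table(clusters) < 3)) stopf("every cluster needs >= 3 cells")
    expm <- expm1(lc)
    n <- ncol(lc)
    # rank once per gene across all cells; rank-sum statistics per cluster
    # then follow from the group's rank totals (tie-corrected variance)
    R <- t(apply(lc, 1, rank))               # genes x cells, average ties
    tie_term <- apply(lc, 1, function(v) {
        t <- table(v); sum(t^3 - t)
    })
    out <- list()
    for (cl in labs) {
        idx <- clusters == cl
        n1 <- sum(idx); n2 <- n - n1
        mean_in <- rowMeans(expm[, idx, drop = FALSE])
        mean_out <- rowMeans(expm[, !idx, drop = FALSE])
        fold <- (mean_in + eps) / (mean_out + eps)
        if (test == "wilcox") {
            W <- rowSums(R[, idx, drop = FALSE]) - n1 * (n1 + 1) / 2
            mu <- n1 * n2 / 2
            sigma <- sqrt((n1 * n2 / 12) *
                ((n + 1) - tie_term / (n * (n - 1))))
            z <- W - mu
            z <- (z - sign(z) * 0.5) / sigma      # continuity correction
            p <- 2 * stats::pnorm(-abs(z))
            p[sigma == 0] <- 1                    # constant gene
            p <- pmin(p, 1)
        } else {
            p <- apply(lc, 1, function(v) {
                if (stats::sd(v[idx]) == 0 && stats::sd(v[!idx]) == 0)
                    return(1)
                stats::t.test(v[idx], v[!idx])$p.value
            })
        }
        adj <- pmax(stats::p.adjust(p, "BH"), 1e-300)
        out[[cl]] <- data.frame(
            gene = rownames(lc), cluster = cl, fold_change = fold,
            p_value = pmax(p, 1e-300), adjusted_p = adj,
            direction = ifelse(fold >= 1, "up", "down"),
            row.names = NULL)
    }
    do.call(rbind, unname(out))
}

#' Default signature dictionary for identity assignment
#'
#' The characteristic-gene dictionary for the seven cell families:
#' mesenchymal stem cells (Pdgfra, Prrx1), satellite cells/stromal
#' progenitors (Pax7), Schwann cells/neural progenitors (Plp1, Cnp, Dhh),
#' myofibroblasts (Acta2, Mylk), endothelial/vascular progenitor cells
#' (Cdh5, Pecam1, Cd34), lymphocytes (Ms4a1) and myeloid cells (Ccr2,
#' Mrc1, Fcgr1, Ccr1, S100a9, Cd209a).
#'
#' @return named list of character vectors (identity label -> genes).
#' @export
defaultSignatures <- function() {
    list(
        "Mesenchymal stem cells" = c("Pdgfra", "Prrx1"),
        "Satellite cells/stromal progenitors" = "Pax7",
        "Schwann cells/neural progenitors" = c("Plp1", "Cnp", "Dhh"),
        "Myofibroblasts" = c("Acta2", "Mylk"),
        "Endothelial/vascular progenitor cells" = c("Cdh5", "Pecam1", "Cd34"),
        "Lymphocytes" = "Ms4a1",
        "Myeloid cells" = c("Ccr2", "Mrc1", "Fcgr1", "Ccr1", "S100a9",
                            "Cd209a"))
}

#' Read / write an editable signature table
#'
#' TSV with columns `identity` and `genes` (comma-separated).
#'
#' @param signatures named list as returned by [defaultSignatures()].
#' @param path file path.
#' @return `readSignatures` returns the named list.
#' @export
writeSignatures <- function(signatures, path) {
    utils::write.table(
        data.frame(identity = names(signatures),
                   genes = vapply(signatures, paste, "", collapse = ",")),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignatures
#' @export
readSignatures <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
    stats::setNames(strsplit(d$genes, ","), d$identity)
}

#' Assign a cell-type identity to each cluster from marker statistics
#'
#' The score of (cluster, identity) is the mean `-log10(adjusted_p)` over
#' the identity's signature genes restricted to genes upregulated
#' (`fold_change > 1`) in the cluster; the identity with the highest score
#' wins, ties broken by higher mean fold change; a cluster with no
#' upregulated signature gene of any identity is flagged unassigned.
#'
#' @param stats output of [differentialMarkers()].
#' @param signatures named list (identity -> genes); default
#'   [defaultSignatures()].
#' @return data.frame with columns `cluster`, `identity` (NA when
#'   unassigned), `score`, `n_genes` (signature genes supporting the call).
#' @export
assignIdentity <- function(stats, signatures = defaultSignatures()) {
    if (!length(signatures)) stopf("empty signature table")
    out <- list()
    for (cl in unique(stats$cluster)) {
        s <- stats[stats$cluster == cl & stats$fold_change > 1, ]
        best <- NA_character_; best_score <- -Inf; best_fold <- -Inf
        best_n <- 0L
        for (id in names(signatures)) {
            hit <- s[s$gene %in% signatures[[id]], ]
            if (!nrow(hit)) next
            score <- mean(-log10(hit$adjusted_p))
            fold <- mean(hit$fold_change)
            if (score > best_score ||
                (score == best_score && fold > best_fold)) {
                best <- id; best_score <- score; best_fold <- fold
                best_n <- nrow(hit)
            }
        }
        out[[cl]] <- data.frame(cluster = cl, identity = best,
            score = if (is.finite(best_score)) best_score else NA_real_,
            n_genes = best_n, row.names = NULL)
    }
    do.call(rbind, unname(out))
}

#' Timecourse log2 fold-change heatmap matrix for one cluster
#'
#' For each requested gene and day, the log2 ratio of mean
#' back-transformed expression at that day versus day 0, within one
#' cluster: `log2((mean_d + eps) / (mean_0 + eps))`. The day-0 column is
#' zero by construction; a day where the cluster is absent is masked NA.
#'
#' @param x genes x cells log-normalized matrix or an object with a
#'   `logcounts` assay.
#' @param clusters label per cell.
#' @param days integer day per cell.
#' @param cluster the cluster to profile.
#' @param genes genes of interest (error if any is absent).
#' @param day_levels days to tabulate; default the sorted unique days.
#' @param eps pseudocount.
#' @return genes x days numeric matrix of log2 fold changes.
#' @export
timecourseLFC <- function(x, clusters, days, cluster, genes,
                          day_levels = NULL, eps = 1e-9) {
    lc <- if (is.matrix(x)) x else SummarizedExperiment::assay(x, "logcounts")
    missing <- setdiff(genes, rownames(lc))
    if (length(missing))
        stopf("gene(s) not in matrix: %s", paste(missing, collapse = ", "))
    if (is.null(day_levels)) day_levels <- sort(unique(days))
    if (!0 %in% day_levels || !any(clusters == cluster & days == 0))
        stopf("day 0 must be present for cluster '%s'", cluster)
    expm <- expm1(lc[genes, , drop = FALSE])
    base <- rowMeans(expm[, clusters == cluster & days == 0, drop = FALSE])
    out <- matrix(NA_real_, length(genes), length(day_levels),
                  dimnames = list(genes, as.character(day_levels)))
    for (d in day_levels) {
        idx <- clusters == cluster & days == d
        if (!any(idx)) next
        out[, as.character(d)] <-
            log2((rowMeans(expm[, idx, drop = FALSE]) + eps) / (base + eps))
    }
    out
}
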