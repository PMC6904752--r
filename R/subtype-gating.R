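#' Default marker gating rules for the mesenchymal family
#'
#' Boolean transcript rules stratifying the mesenchymal progenitor family
#' into tenocytes (Scx+ Col1a1+), MSCs (Pdgfra+ Sox9- Runx2-),
#' chondrocytes (Sox9+ Acan+ Col1a1+ Col3a1+) and preosteoblasts
#' (Runx2+ Col1a1+). The rules are not mutually exclusive (Col1a1 is
#' shared, Runx2/Sox9 co-positivity is possible), so each rule carries a
#' priority rank; when a cell is eligible for several subtypes the lowest
#' rank wins (chondrocyte > preosteoblast > tenocyte > MSC by default).
#'
#' @return data.frame with columns `subtype`, `positive` and `negative`
#'   (comma-separated gene lists) and `priority` (1 = highest).
#' @export
defaultGatingRules <- function() {
    data.frame(
        subtype = c("chondrocyte", "preosteoblast", "tenocyte", "MSC"),
        positive = c("Sox9,Acan,Col1a1,Col3a1", "Runx2,Col1a1",
                     "Scx,Col1a1", "Pdgfra"),
        negative = c("", "", "", "Sox9,Runx2"),
        priority = 1:4)
}

#' Read / write gating rules as an editable TSV
#'
#' @param rules data.frame as returned by [defaultGatingRules()].
#' @param path file path.
#' @return `readGatingRules` returns the data.frame.
#' @export
writeGatingRules <- function(rules, path) {
    utils::write.table(rules, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeGatingRules
#' @export
readGatingRules <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c(subtype = "character",
                                     positive = "character",
                                     negative = "character",
                                     priority = "integer"),
                      na.strings = NULL)
}

.splitGenes <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",")[[1]]
}

#' Gate cells into subtypes by boolean marker rules
#'
#' A cell is positive for a gene when its raw count exceeds
#' `positivity_cutoff` (default 0, i.e. detection). A cell is eligible for
#' a subtype iff all its required-positive genes are positive and all its
#' required-negative genes are not; among multiple eligible subtypes the
#' highest-priority (lowest rank) wins; a cell eligible for none is
#' `unclassified`. The result is a full partition: every cell receives
#' exactly one label.
#'
#' @param counts genes x cells matrix of raw counts (or an object with a
#'   `counts` assay), typically restricted to the mesenchymal family.
#' @param rules gating rules data.frame (see [defaultGatingRules()]).
#' @param positivity_cutoff count threshold for positivity.
#' @return factor of subtype labels per cell, levels = rule subtypes in
#'   priority order plus `"unclassified"`.
#' @export
gateSubtypes <- function(counts, rules = defaultGatingRules(),
                         positivity_cutoff = 0) {
    m <- if (methods::is(counts, "SummarizedExperiment"))
        SummarizedExperiment::assay(counts, "counts") else counts
    all_genes <- unique(unlist(lapply(
        c(rules$positive, rules$negative), .splitGenes)))
    missing <- setdiff(all_genes, rownames(m))
    if (length(missing))
        stopf("gating rule references absent gene(s): %s",
              paste(missing, collapse = ", "))
    for (i in seq_len(nrow(rules))) {
        pos <- .splitGenes(rules$positive[i])
        neg <- .splitGenes(rules$negative[i])
        if (length(intersect(pos, neg)))
            stopf("rule '%s': positive and negative genes overlap",
                  rules$subtype[i])
    }
    positive <- as.matrix(m[all_genes, , drop = FALSE] > positivity_cutoff)
    rules <- rules[order(rules$priority), , drop = FALSE]
    n <- ncol(m)
    label <- rep("unclassified", n)
    open <- rep(TRUE, n)
    for (i in seq_len(nrow(rules))) {
        pos <- .splitGenes(rules$positive[i])
        neg <- .splitGenes(rules$negative[i])
        ok <- open
        for (g in pos) ok <- ok & positive[g, ]
        for (g in neg) ok <- ok & !positive[g, ]
        label[ok] <- rules$subtype[i]
        open <- open & !ok
    }
    factor(label, levels = c(rules$subtype, "unclassified"))
}

#' Per-day subtype counts and target-gene expression profile
#'
#' Tabulates gated subtype labels per day (rows sum to the cells gated
#' that day) and summarizes a target gene per (subtype, day) stratum:
#' cell count, fraction of cells expressing the gene above a positivity
#' cutoff, and the median and mean log expression over all cells of the
#' stratum.
#'
#' @param labels factor from [gateSubtypes()].
#' @param days integer day per cell.
#' @param x genes x cells log-normalized matrix (or object with a
#'   `logcounts` assay) for the expression summary; `NULL` to skip.
#' @param target_gene gene to profile (default `"Vegfa"`).
#' @param day_levels days to tabulate; missing days yield zero rows.
#' @param positivity_cutoff log-expression cutoff defining "expressing".
#' @return list with `counts` (day x subtype integer matrix, including
#'   `unclassified`) and `profile` (data.frame subtype/day/n/
#'   fraction_expressing/median_log/mean_log; NULL when `x` is NULL).
#' @export
subtypeSummary <- function(labels, days, x = NULL, target_gene = "Vegfa",
                           day_levels = NULL, positivity_cutoff = 0) {
    if (length(labels) != length(days))
        stopf("labels and days must be parallel")
    if (is.null(day_levels)) day_levels <- sort(unique(days))
    dfac <- factor(days, levels = day_levels)
    counts <- table(day = dfac, subtype = labels)
    counts <- matrix(as.integer(counts), nrow = nrow(counts),
                     dimnames = dimnames(counts))
    profile <- NULL
    if (!is.null(x)) {
        lc <- if (is.matrix(x)) x
            else SummarizedExperiment::assay(x, "logcounts")
        if (!target_gene %in% rownames(lc))
            stopf("target gene '%s' not in matrix", target_gene)
        v <- lc[target_gene, ]
        rows <- list()
        for (st in levels(labels)) for (d in day_levels) {
            idx <- labels == st & days == d
            rows[[paste(st, d)]] <- data.frame(
                subtype = st, day = d, n = sum(idx),
                fraction_expressing = if (any(idx))
                    mean(v[idx] > positivity_cutoff) else NA_real_,
                median_log = if (any(idx)) stats::median(v[idx]) else NA_real_,
                mean_log = if (any(idx)) mean(v[idx]) else NA_real_)
        }
        profile <- do.call(rbind, unname(rows))
    }
    list(counts = counts, profile = profile)
}
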