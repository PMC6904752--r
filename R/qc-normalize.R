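#' Quality-control parameters
#'
#' Cell-level rules remove cells with fewer than `min_genes_per_cell`
#' detected genes, more than `max_mito_fraction` of UMIs on mitochondrial
#' genes, or more than `max_umis_per_cell` total UMIs; the gene-level rule
#' then removes genes expressed (count > 0) in fewer than
#' `min_cells_per_gene` of the surviving cells. All boundaries are strict:
#' equality retains (a 500-gene cell stays, a 10% mito cell stays, a 60 000
#' UMI cell stays).
#'
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param max_mito_fraction maximum mitochondrial UMI fraction.
#' @param max_umis_per_cell maximum UMIs per cell.
#' @param min_cells_per_gene minimum expressing cells per gene.
#' @return a `QCParams` list.
#' @export
qcParams <- function(min_genes_per_cell = 500L, max_mito_fraction = 0.10,
                     max_umis_per_cell = 60000L, min_cells_per_gene = 10L) {
    if (min_genes_per_cell <= 0 || max_umis_per_cell <= 0 ||
        min_cells_per_gene <= 0)
        stopf("all QC thresholds must be positive")
    if (max_mito_fraction < 0 || max_mito_fraction > 1)
        stopf("max_mito_fraction must lie in [0, 1]")
    structure(list(min_genes_per_cell = min_genes_per_cell,
                   max_mito_fraction = max_mito_fraction,
                   max_umis_per_cell = max_umis_per_cell,
                   min_cells_per_gene = min_cells_per_gene),
              class = "QCParams")
}

#' Apply quality-control filters to a count matrix
#'
#' Cells violating any cell rule are removed first; genes expressed in
#' fewer than the minimum number of *surviving* cells are removed next.
#' Because dropping genes can in turn change per-cell detected-gene counts,
#' the two passes iterate to a fixed point, so the result is stable under
#' re-application.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with integer
#'   `counts`; mitochondrial genes are taken from the rowData `mito` flag
#'   when present, else from the `mt-` name prefix.
#' @param params a [qcParams()].
#' @return the filtered object. Its metadata gains a `qc_report` with one
#'   row per removed cell (barcode, reason) and the removed genes.
#' @export
applyQC <- function(sce, params = qcParams()) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    rd <- SummarizedExperiment::rowData(sce)
    removed_cells <- data.frame(barcode = character(), reason = character())
    removed_genes <- character()
    repeat {
        mito <- if ("mito" %in% colnames(SummarizedExperiment::rowData(sce)))
            SummarizedExperiment::rowData(sce)$mito
        else startsWith(rownames(sce), "mt-")
        counts <- SummarizedExperiment::assay(sce, "counts")
        n_genes <- Matrix::colSums(counts > 0)
        total <- Matrix::colSums(counts)
        mito_frac <- ifelse(total > 0,
            Matrix::colSums(counts[mito, , drop = FALSE]) / total, 1)
        bad_genes_cell <- n_genes < params$min_genes_per_cell
        bad_mito <- mito_frac > params$max_mito_fraction
        bad_umis <- total > params$max_umis_per_cell
        drop_cell <- bad_genes_cell | bad_mito | bad_umis
        if (any(drop_cell)) {
            reason <- ifelse(bad_genes_cell, "low_genes",
                      ifelse(bad_mito, "high_mito", "high_umis"))
            removed_cells <- rbind(removed_cells,
                data.frame(barcode = colnames(sce)[drop_cell],
                           reason = reason[drop_cell]))
            sce <- sce[, !drop_cell]
        }
        if (ncol(sce) == 0)
            stopf("empty after QC: every cell violated a filter")
        counts <- SummarizedExperiment::assay(sce, "counts")
        expressing <- Matrix::rowSums(counts > 0)
        drop_gene <- expressing < params$min_cells_per_gene
        if (any(drop_gene)) {
            removed_genes <- c(removed_genes, rownames(sce)[drop_gene])
            sce <- sce[!drop_gene, ]
        }
        if (nrow(sce) == 0)
            stopf("empty after QC: every gene fell below min_cells_per_gene")
        if (!any(drop_cell) && !any(drop_gene)) break
    }
    S4Vectors::metadata(sce)$qc_report <-
        list(removed_cells = removed_cells, removed_genes = removed_genes,
             params = params)
    sce
}

#' Log-normalize a QC'd count matrix
#'
#' Per-cell depth normalization to a common scale factor followed by a
#' log transform: `value = ln(1 + scale_factor * count / total)`. Zero
#' counts map to zero, and the back-transform recovers the scale factor
#' exactly: `sum(expm1(value)) == scale_factor` for every cell.
#'
#' @param sce the filtered object.
#' @param scale_factor target per-cell total (default 10 000).
#' @return the object with an added dense `logcounts` assay and the scale
#'   factor in its metadata.
#' @export
normalizeLog <- function(sce, scale_factor = 10000) {
    if (scale_factor <= 0) stopf("scale_factor must be positive")
    counts <- SummarizedExperiment::assay(sce, "counts")
    total <- Matrix::colSums(counts)
    if (any(total == 0)) stopf("cell with zero total counts")
    lc <- log1p(as.matrix(counts) %*% Matrix::Diagonal(x = scale_factor / total))
    lc <- as.matrix(lc)
    dimnames(lc) <- dimnames(counts)
    SummarizedExperiment::assay(sce, "logcounts") <- lc
    S4Vectors::metadata(sce)$scale_factor <- scale_factor
    sce
}

#' Select highly variable genes by log-space variance
#'
#' @param logcounts genes x cells matrix of log-normalized values.
#' @param n_hvg number of genes to keep (capped at the gene count).
#' @return character vector of gene names, ordered by decreasing variance.
#' @export
selectHVG <- function(logcounts, n_hvg = 2000L) {
    v <- apply(logcounts, 1, stats::var)
    head(names(sort(v, decreasing = TRUE)), n_hvg)
}

#' PCA embedding of a log-normalized matrix
#'
#' Restricts to the top `n_hvg` genes by log-space variance, standardizes
#' each gene to zero mean and unit variance with z-scores clipped at
#' `clip`, and computes principal components. The sign of each component is
#' fixed so its largest-magnitude gene loading is positive, making the
#' embedding deterministic and invariant to gene order.
#'
#' @param sce object with a `logcounts` assay, or a plain genes x cells
#'   matrix of log values.
#' @param n_hvg highly variable genes to use (default 2000).
#' @param n_components components to return (default 20; reduced to the
#'   matrix rank with a warning when the data carry fewer dimensions).
#' @param clip absolute z-score cap before PCA.
#' @param hvg optional explicit gene set overriding internal selection.
#' @return list with `coordinates` (cells x components), `variances`
#'   (non-increasing component variances), `rotation`, and `hvg`.
#' @export
embedPCA <- function(sce, n_hvg = 2000L, n_components = 20L, clip = 10,
                     hvg = NULL) {
    lc <- if (is.matrix(sce)) sce
        else SummarizedExperiment::assay(sce, "logcounts")
    if (is.null(hvg)) {
        if (n_hvg > nrow(lc)) n_hvg <- nrow(lc)
        hvg <- selectHVG(lc, n_hvg)
    } else if (!all(hvg %in% rownames(lc)))
        stopf("hvg contains genes absent from the matrix")
    x <- t(lc[hvg, , drop = FALSE])          # cells x genes
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- Inf                       # constant gene -> all-zero z
    z <- sweep(sweep(x, 2, mu), 2, sd, "/")
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    vars <- pc$sdev^2
    rank <- sum(vars > max(vars) * 1e-12)
    if (n_components > rank) {
        warnf("requested %d components but rank is %d; returning %d",
              n_components, rank, rank)
        n_components <- rank
    }
    k <- seq_len(n_components)
    rot <- pc$rotation[, k, drop = FALSE]
    coords <- pc$x[, k, drop = FALSE]
    for (j in k) {                            # fixed sign convention
        i <- which.max(abs(rot[, j]))
        if (rot[i, j] < 0) {
            rot[, j] <- -rot[, j]
            coords[, j] <- -coords[, j]
        }
    }
    rownames(coords) <- colnames(lc)
    list(coordinates = coords, variances = vars[k], rotation = rot,
         hvg = hvg)
}
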