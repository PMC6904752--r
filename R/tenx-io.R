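#' Write a count matrix as a 10x-style directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, genes as rows),
#' `features.tsv` (gene id, gene name), `barcodes.tsv`, and — when the
#' object carries them — `truth.tsv` (barcode, family, subtype, day,
#' replicate) with the ground-truth labels. A paired [readTenx()]
#' round-trips the counts, gene order and barcode order exactly.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay of nonnegative integers.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeTenx <- function(sce, dir) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    barcodes <- colnames(sce)
    if (is.null(barcodes)) barcodes <- character(0)
    if (anyDuplicated(barcodes)) stopf("duplicate barcodes")
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stopf("cannot create directory '%s'", dir)
    m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "TsparseMatrix")
    con <- file(file.path(dir, "matrix.mtx"), "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)), con)
    if (length(m@x)) {
        ord <- order(m@j, m@i)   # column-major, the conventional MTX order
        writeLines(sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L,
                           as.integer(m@x[ord])), con)
    }
    genes <- rownames(sce)
    utils::write.table(
        data.frame(id = genes, name = genes),
        file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(barcodes, file.path(dir, "barcodes.tsv"))
    cd <- SummarizedExperiment::colData(sce)
    if (all(c("family", "day", "replicate") %in% colnames(cd))) {
        tr <- data.frame(barcode = barcodes,
                         family = cd$family,
                         subtype = if ("subtype" %in% colnames(cd))
                             cd$subtype else NA,
                         day = cd$day, replicate = cd$replicate)
        utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}

#' Read a 10x-style directory back into a SingleCellExperiment
#'
#' @param dir directory written by [writeTenx()] (or any MTX +
#'   features/barcodes triplet with genes as rows).
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`; ground-truth columns are restored to colData when a
#'   `truth.tsv` is present, and the mitochondrial rowData flag is rebuilt
#'   from the `mt-` gene-name prefix.
#' @export
readTenx <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    if (!file.exists(mtx)) stopf("no matrix.mtx under '%s'", dir)
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                               colClasses = "character")
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    if (nrow(feats) != nrow(counts) || length(barcodes) != ncol(counts))
        stopf("matrix dimensions disagree with features/barcodes")
    dimnames(counts) <- list(feats[[2]], barcodes)
    cd <- DataFrame(barcode = barcodes, row.names = barcodes)
    tpath <- file.path(dir, "truth.tsv")
    if (file.exists(tpath)) {
        tr <- utils::read.table(tpath, sep = "\t", header = TRUE,
                                colClasses = c(barcode = "character",
                                               replicate = "character"))
        stopifnot(identical(tr$barcode, barcodes))
        cd$family <- tr$family
        cd$subtype <- tr$subtype
        cd$day <- as.integer(tr$day)
        cd$replicate <- tr$replicate
    }
    rd <- DataFrame(gene = feats[[2]], mito = startsWith(feats[[2]], "mt-"),
                    row.names = feats[[2]])
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
}
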