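# shared fixtures and independent oracles

# small, fast simulation configs
smallConfig <- function(seed = 1, ...) {
    simConfig(cells_per_replicate = 120L, timepoints = c(0L, 3L),
              seed = seed, ...)
}

# brute-force Spearman: rank with average ties, then Pearson on the ranks
bruteSpearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force Yen threshold: evaluate the entropic-correlation criterion
# at every split point by direct summation over the histogram
bruteYen <- function(image, n_bins = 256L) {
    v <- as.vector(image)
    rng <- range(v)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    p <- tabulate(idx, nbins = n_bins) / length(v)
    best <- -Inf; best_t <- NA
    for (t in seq_len(n_bins - 1L)) {
        P1 <- sum(p[1:t]); s1 <- sum(p[1:t]^2); s2 <- sum(p[(t + 1):n_bins]^2)
        if (P1 <= 0 || P1 >= 1 || s1 <= 0 || s2 <= 0) next
        crit <- 2 * log(P1 * (1 - P1)) - log(s1) - log(s2)
        if (crit > best + 1e-12) { best <- crit; best_t <- t }
    }
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    centers[best_t]
}

# simple two-blob embedding with zero within-class variance
twoBlobCoords <- function(n1 = 20, n2 = 30, sep = 10) {
    coords <- rbind(matrix(0, n1, 2), matrix(sep, n2, 2))
    rownames(coords) <- sprintf("c%03d", seq_len(n1 + n2))
    coords
}

# a tiny SingleCellExperiment from a dense count matrix
makeSCE <- function(counts, day = 0L, replicate = "r1") {
    genes <- rownames(counts)
    if (is.null(genes)) {
        genes <- sprintf("g%03d", seq_len(nrow(counts)))
        rownames(counts) <- genes
    }
    bcs <- colnames(counts)
    if (is.null(bcs)) {
        bcs <- sprintf("bc%03d", seq_len(ncol(counts)))
        colnames(counts) <- bcs
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = S4Vectors::DataFrame(barcode = bcs, day = day,
                                       replicate = replicate,
                                       row.names = bcs),
        rowData = S4Vectors::DataFrame(gene = genes,
                                       mito = startsWith(genes, "mt-"),
                                       row.names = genes))
}

# constructed fixture: 20 cells x 520 genes; planted violations — a
# 499-gene cell, a just-over-10%-mito cell, a 60 001-UMI cell — plus two
# boundary cells that must survive (exactly 500 genes; exactly 10% mito)
# and one gene expressed in exactly 9 of the 17 surviving cells
qcFixture <- function() {
    G <- 520L; n <- 20L
    counts <- matrix(1L, G, n,
                     dimnames = list(c(sprintf("mt-%d", 1:2),
                                       sprintf("g%03d", seq_len(G - 2L))),
                                     sprintf("cell%02d", seq_len(n))))
    counts[, 1] <- 0L; counts[seq_len(499), 1] <- 1L   # 499 genes: removed
    counts[, 4] <- 0L; counts[seq_len(500), 4] <- 1L   # 500 genes: retained
    counts["g500", ] <- 0L
    counts["g500", 6:14] <- 2L           # 9 surviving cells express g500
    # cell 3: exactly 60 001 UMIs (> 60 000: removed)
    counts["g010", 3] <- counts["g010", 3] + (60001L - sum(counts[, 3]))
    # cell 2: mito fraction just above 10% (removed)
    nonmito2 <- sum(counts[3:G, 2])
    counts["mt-1", 2] <- 0L
    counts["mt-2", 2] <- as.integer(ceiling(nonmito2 / 9) + 1L)
    # cell 5: mito fraction exactly 10% (retained)
    nm5 <- sum(counts[3:G, 5])
    pad <- (9L - nm5 %% 9L) %% 9L
    counts["g011", 5] <- counts["g011", 5] + pad
    counts["mt-1", 5] <- 0L
    counts["mt-2", 5] <- (nm5 + pad) %/% 9L
    counts
}
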