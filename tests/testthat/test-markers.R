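test_that("rank-sum marker test matches stats::wilcox.test exactly", {
    set.seed(60)
    n1 <- 15; n2 <- 25
    lc <- rbind(g1 = c(rnorm(n1, 2), rnorm(n2, 0)),
                g2 = rnorm(n1 + n2),
                g3 = sample(0:3, n1 + n2, replace = TRUE))  # heavy ties
    colnames(lc) <- sprintf("c%02d", seq_len(n1 + n2))
    cl <- rep(c("a", "b"), c(n1, n2))
    res <- differentialMarkers(lc, cl)
    for (g in rownames(lc)) {
        p_ref <- stats::wilcox.test(lc[g, cl == "a"], lc[g, cl == "b"],
                                    exact = FALSE, correct = TRUE)$p.value
        expect_equal(res$p_value[res$gene == g & res$cluster == "a"],
                     p_ref, tolerance = 1e-12)
    }
})

test_that("fold changes follow the pseudocounted ratio of expm1 means", {
    lc <- rbind(g1 = log1p(c(4, 4, 4, 1, 1, 1)),
                g2 = log1p(c(0, 0, 0, 0, 0, 0)))
    colnames(lc) <- sprintf("c%d", 1:6)
    cl <- rep(c("a", "b"), each = 3)
    res <- differentialMarkers(lc, cl)
    expect_equal(res$fold_change[res$gene == "g1" & res$cluster == "a"],
                 (4 + 1e-9) / (1 + 1e-9), tolerance = 1e-9)
    # identically zero gene: fold 1, p 1
    row <- res[res$gene == "g2" & res$cluster == "a", ]
    expect_equal(row$fold_change, 1)
    expect_equal(row$adjusted_p, 1)
})

test_that("BH adjustment is monotone and bounded below by the raw p", {
    set.seed(61)
    lc <- matrix(rnorm(100 * 40), 100, 40,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("c%02d", 1:40)))
    cl <- rep(c("a", "b"), each = 20)
    res <- differentialMarkers(lc, cl)
    a <- res[res$cluster == "a", ]
    expect_true(all(a$adjusted_p >= a$p_value - 1e-15))
    ord <- order(a$p_value)
    expect_true(all(diff(a$adjusted_p[ord]) >= -1e-12))
    expect_equal(a$adjusted_p, pmax(p.adjust(a$p_value, "BH"), 1e-300))
})

test_that("planted markers are recovered with calibrated fold and low FDR", {
    sim <- simulateTimecourse(simConfig(cells_per_replicate = 1000L,
                                        timepoints = c(0L, 3L), seed = 71L))
    s <- normalizeLog(applyQC(sim$matrices[[1]]))
    lc <- SummarizedExperiment::assay(s, "logcounts")
    fam <- s$family
    res <- differentialMarkers(lc, ifelse(fam == "schwann", "schwann", "rest"))
    markers <- intersect(c("Plp1", "Cnp", "Dhh"), res$gene)
    hit <- res[res$cluster == "schwann" & res$gene %in% markers, ]
    expect_true(all(hit$adjusted_p < 0.05))
    expect_true(all(hit$fold_change > 3 & hit$fold_change < 7))
})

test_that("degenerate inputs are rejected", {
    lc <- matrix(rnorm(20), 4, 5)
    rownames(lc) <- sprintf("g%d", 1:4); colnames(lc) <- sprintf("c%d", 1:5)
    expect_error(differentialMarkers(lc, rep("a", 5)), "2 clusters")
    expect_error(differentialMarkers(lc, c("a", "a", "b", "b", "b")[1:4]),
                 "one cluster label per cell")
    expect_error(differentialMarkers(lc, c("a", "a", "b", "b", "b")),
                 ">= 3 cells")
})

test_that("identity assignment maps signature genes to the right labels", {
    mk <- function(gene, cluster, fold, p)
        data.frame(gene = gene, cluster = cluster, fold_change = fold,
                   p_value = p, adjusted_p = p,
                   direction = ifelse(fold >= 1, "up", "down"))
    stats <- rbind(
        mk(c("Plp1", "Cnp", "Dhh"), "f1", c(22, 12, 2.7), 1e-50),
        mk(c("Cdh5", "Pecam1", "Cd34"), "f2", c(11, 10, 2.5), 1e-40),
        mk("gene0001", "f3", 5, 1e-30))
    ids <- assignIdentity(stats)
    expect_equal(ids$identity[ids$cluster == "f1"],
                 "Schwann cells/neural progenitors")
    expect_equal(ids$identity[ids$cluster == "f2"],
                 "Endothelial/vascular progenitor cells")
    expect_true(is.na(ids$identity[ids$cluster == "f3"]))
    expect_error(assignIdentity(stats, list()), "empty")
    # invariant to gene order
    ids2 <- assignIdentity(stats[rev(seq_len(nrow(stats))), ])
    expect_equal(ids2[order(ids2$cluster), "identity"],
                 ids[order(ids$cluster), "identity"])
})

test_that("timecourse LFC is zero at day 0, log2-scaled, and masks gaps", {
    lc <- rbind(g1 = log1p(c(2, 2, 4, 4, 8, 8)),
                g2 = log1p(rep(1, 6)))
    colnames(lc) <- sprintf("c%d", 1:6)
    cl <- rep("A", 6)
    days <- c(0, 0, 3, 3, 7, 7)
    h <- timecourseLFC(lc, cl, days, cluster = "A", genes = c("g1", "g2"),
                       day_levels = c(0, 3, 7, 21))
    expect_equal(unname(h[, "0"]), c(0, 0))
    expect_equal(h["g1", "3"], 1, tolerance = 1e-6)   # mean doubled
    expect_equal(h["g1", "7"], 2, tolerance = 1e-6)
    expect_true(all(is.na(h[, "21"])))                # cluster absent
    expect_error(timecourseLFC(lc, cl, days, "A", "absent_gene"),
                 "absent_gene")
    expect_error(timecourseLFC(lc, cl, days + 3, "A", "g1"), "day 0")
})

test_that("signature tables round-trip through TSV", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSignatures(defaultSignatures(), path)
    back <- readSignatures(path)
    expect_equal(back, defaultSignatures())
})

test_that("the shipped signature table matches the built-in defaults", {
    path <- system.file("extdata", "signatures.tsv",
                        package = "scConsolidate")
    expect_true(nzchar(path))
    expect_equal(readSignatures(path), defaultSignatures())
})
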