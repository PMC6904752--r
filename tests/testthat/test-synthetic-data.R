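test_that("fixed seed reproduces the timecourse byte-identically", {
    cfg <- simConfig(cells_per_replicate = 100L, timepoints = c(0L, 3L),
                     seed = 7L)
    a <- simulateTimecourse(cfg)
    b <- simulateTimecourse(cfg)
    expect_identical(names(a$matrices), names(b$matrices))
    for (u in names(a$matrices))
        expect_identical(
            as.matrix(SummarizedExperiment::assay(a$matrices[[u]], "counts")),
            as.matrix(SummarizedExperiment::assay(b$matrices[[u]], "counts")))
    expect_identical(as.data.frame(a$cell_truth), as.data.frame(b$cell_truth))
})

test_that("requested dimensions and unit structure are honored", {
    cfg <- simConfig(n_genes = 500L, cells_per_replicate = 100L, seed = 3L)
    sim <- simulateTimecourse(cfg)
    expect_length(sim$matrices, 4 * 2)   # 4 days x 2 replicates
    for (s in sim$matrices) {
        expect_equal(dim(s), c(500L, 100L))
        expect_false(anyDuplicated(colnames(s)) > 0)
    }
    expect_setequal(unique(sim$cell_truth$day), c(0L, 3L, 7L, 21L))
})

test_that("realized marker fold tracks the generative fold at large n", {
    cfg <- simConfig(cells_per_replicate = 1000L, timepoints = c(0L, 3L),
                     seed = 11L)
    sim <- simulateTimecourse(cfg)
    counts <- do.call(cbind, lapply(sim$matrices, function(s)
        as.matrix(SummarizedExperiment::assay(s, "counts"))))
    fam <- sim$cell_truth$family
    markers <- rownames(counts)[sim$gene_truth$marker_of %in% "schwann" &
                                !is.na(sim$gene_truth$marker_of)]
    in_fam <- fam == "schwann"
    expect_gt(sum(in_fam), 200)
    ratio <- mean(counts[markers, in_fam]) / mean(counts[markers, !in_fam])
    expect_gt(ratio, 4)     # generative fold 5, tolerance 25%
    expect_lt(ratio, 6)
})

test_that("composition converges to the configured proportions", {
    cfg <- simConfig(cells_per_replicate = 2000L, timepoints = 0L,
                     replicates_per_timepoint = 1L, seed = 5L)
    sim <- simulateTimecourse(cfg)
    realized <- prop.table(table(sim$cell_truth$family))
    expected <- cfg$composition[, "0"]
    for (f in names(expected))
        expect_lt(abs(realized[[f]] - expected[[f]]),
                  3 * sqrt(expected[[f]] * (1 - expected[[f]]) / 2000) + 1e-9)
})

test_that("invalid configurations are rejected", {
    comp <- matrix(1, 1, 1)
    expect_error(simConfig(composition = comp), "composition")
    fams <- defaultFamilies()
    fams$satellite$markers <- fams$msc$markers[1]
    expect_error(simConfig(families = fams), "overlap")
    expect_error(simConfig(families = list()), "family")
    expect_error(simConfig(mito_fraction_range = c(0.5, 0.2)), "interval")
    expect_error(familySpec("x", character()), "marker")
})

test_that("mitochondrial fraction tracks the configured range", {
    cfg <- simConfig(cells_per_replicate = 400L, timepoints = 0L, seed = 9L)
    sim <- simulateTimecourse(cfg)
    s <- sim$matrices[[1]]
    counts <- as.matrix(SummarizedExperiment::assay(s, "counts"))
    mito <- SummarizedExperiment::rowData(s)$mito
    frac <- colSums(counts[mito, ]) / colSums(counts)
    # target fractions are U(0.02, 0.08); counts add NB noise around them
    expect_gt(mean(frac), 0.02); expect_lt(mean(frac), 0.08)
    expect_gt(mean(frac > 0.005 & frac < 0.15), 0.97)
    # exact mode pins the fraction at the interval midpoint
    ex <- simulateTimecourse(simConfig(cells_per_replicate = 50L,
        timepoints = 0L, exact = TRUE, batch_effect_sd = 0, seed = 9L))
    cx <- as.matrix(SummarizedExperiment::assay(ex$matrices[[1]], "counts"))
    fx <- colSums(cx[mito, ]) / colSums(cx)
    expect_lt(max(abs(fx - 0.05)), 0.01)
})

test_that("SimConfig round-trips through its text representation", {
    cfg <- simConfig(cells_per_replicate = 77L, seed = 13L,
                     batch_effect_sd = 0.05)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeSimConfig(cfg, path)
    cfg2 <- readSimConfig(path)
    expect_equal(cfg2$cells_per_replicate, 77L)
    expect_equal(cfg2$composition, cfg$composition)
    expect_equal(cfg2$families$msc$subtypes$weights,
                 cfg$families$msc$subtypes$weights)
    # identical simulated output from the round-tripped config
    a <- simulateTimecourse(cfg)
    b <- simulateTimecourse(cfg2)
    expect_identical(
        as.matrix(SummarizedExperiment::assay(a$matrices[[1]], "counts")),
        as.matrix(SummarizedExperiment::assay(b$matrices[[1]], "counts")))
})

test_that("cytometry simulation respects fractions and determinism", {
    ev <- simulateCytometry(10000, c(EPC = 0.05, endo = 0.1), seed = 2L)
    ev2 <- simulateCytometry(10000, c(EPC = 0.05, endo = 0.1), seed = 2L)
    expect_identical(ev, ev2)
    # EPC fraction applies to the live compartment
    n_epc <- sum(ev$truth == "EPC")
    expected <- 10000 * 0.05 * 0.9
    expect_lt(abs(n_epc - expected), 3 * sqrt(expected))
    none <- simulateCytometry(2000, c(EPC = 0, endo = 0), seed = 3L)
    expect_false(any(none$truth %in% c("EPC", "endo")))
    expect_error(simulateCytometry(100, c(EPC = 0.7, endo = 0.5)), "sum")
})

test_that("image simulation is bimodal, deterministic and mask-consistent", {
    im <- simulateImage(c(40L, 40L), 0.25, fg_mean = 200, bg_mean = 10,
                        noise_sd = 0, seed = 4L)
    expect_identical(sort(unique(as.vector(im$image))), c(10, 200))
    expect_equal(mean(im$image == 200), 0.25)
    expect_true(all(im$image[im$mask] == 200))
    im2 <- simulateImage(c(40L, 40L), 0.25, fg_mean = 200, bg_mean = 10,
                         noise_sd = 0, seed = 4L)
    expect_identical(im, im2)
    expect_error(simulateImage(fg_mean = 5, bg_mean = 10), "exceed")
})

test_that("the shipped default configuration parses and validates", {
    path <- system.file("extdata", "default_sim_config.yaml",
                        package = "scConsolidate")
    expect_true(nzchar(path))
    cfg <- readSimConfig(path)
    expect_s3_class(cfg, "SimConfig")
    expect_equal(cfg$timepoints, c(0L, 3L, 7L, 21L))
    expect_equal(cfg$cells_per_replicate, 500L)
})
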