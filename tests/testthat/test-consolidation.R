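test_that("k-means backend recovers noise-free blobs exactly and is seeded", {
    coords <- twoBlobCoords(20, 30)
    cl <- clusterCells(coords, k = 2, seed = 1)
    truth <- rep(0:1, c(20, 30))
    expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
    cl2 <- clusterCells(coords, k = 2, seed = 1)
    expect_identical(cl$labels, cl2$labels)
    expect_error(clusterCells(coords, k = 100), "more clusters")
    # labels contiguous from 0
    expect_setequal(unique(cl$labels), 0:1)
})

test_that("graph backend also separates noise-free blobs", {
    coords <- twoBlobCoords(25, 25)
    cl <- clusterCells(coords, method = "graph", seed = 2)
    truth <- rep(0:1, c(25, 25))
    expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
})

test_that("centroid rank correlation matches a brute-force Spearman", {
    set.seed(10)
    for (rep in 1:5) {
        A <- matrix(rnorm(4 * 30), 4, 30,
                    dimnames = list(0:3, sprintf("g%02d", 1:30)))
        B <- matrix(rnorm(3 * 30), 3, 30,
                    dimnames = list(0:2, sprintf("g%02d", 1:30)))
        ca <- newCentroidSet(A, rep(10L, 4))
        cb <- newCentroidSet(B, rep(10L, 3))
        rho <- corMatrix(centroidRankCorrelation(ca, cb))
        for (i in 1:4) for (j in 1:3)
            expect_equal(rho[i, j], bruteSpearman(A[i, ], B[j, ]),
                         tolerance = 1e-12)
    }
})

test_that("rank correlation handles self, reversal, ties and the 4-gene case", {
    g <- sprintf("g%d", 1:4)
    a <- matrix(c(1, 2, 3, 4), 1, dimnames = list("0", g))
    flip <- matrix(c(4, 3, 2, 1), 1, dimnames = list("0", g))
    swap <- matrix(c(1, 3, 2, 4), 1, dimnames = list("0", g))
    ca <- newCentroidSet(a, 5L)
    expect_equal(corMatrix(centroidRankCorrelation(ca, ca))[1, 1], 1)
    expect_equal(corMatrix(centroidRankCorrelation(
        ca, newCentroidSet(flip, 5L)))[1, 1], -1)
    expect_equal(corMatrix(centroidRankCorrelation(
        ca, newCentroidSet(swap, 5L)))[1, 1], 0.8)
    # ties use average ranks: cor with a tied vector still defined
    tied <- matrix(c(1, 2, 2, 3), 1, dimnames = list("0", g))
    expect_equal(corMatrix(centroidRankCorrelation(
        ca, newCentroidSet(tied, 5L)))[1, 1],
        bruteSpearman(c(1, 2, 3, 4), c(1, 2, 2, 3)))
})

test_that("rank correlation is symmetric and monotone-invariant", {
    set.seed(20)
    A <- matrix(rnorm(3 * 25), 3, 25, dimnames = list(0:2, sprintf("g%d", 1:25)))
    B <- matrix(rnorm(3 * 25), 3, 25, dimnames = list(0:2, sprintf("g%d", 1:25)))
    ca <- newCentroidSet(A, rep(5L, 3)); cb <- newCentroidSet(B, rep(5L, 3))
    expect_equal(corMatrix(centroidRankCorrelation(ca, cb)),
                 t(corMatrix(centroidRankCorrelation(cb, ca))))
    # strictly monotone transform leaves Spearman unchanged
    cb2 <- newCentroidSet(exp(3 * B), rep(5L, 3))
    expect_equal(corMatrix(centroidRankCorrelation(ca, cb)),
                 corMatrix(centroidRankCorrelation(ca, cb2)),
                 tolerance = 1e-12)
})

test_that("zero-variance centroids are reported NA with a warning", {
    g <- sprintf("g%d", 1:5)
    A <- rbind(`0` = c(1, 2, 3, 4, 5), `1` = rep(2, 5))
    colnames(A) <- g
    ca <- newCentroidSet(A, c(5L, 5L))
    expect_warning(m <- centroidRankCorrelation(ca, ca), "zero-variance")
    expect_true(all(is.na(corMatrix(m)[2, ])))
    expect_equal(corMatrix(m)[1, 1], 1)
    # differing gene sets are rejected
    B <- A[, c(2:5, 1)]
    expect_error(centroidRankCorrelation(ca, newCentroidSet(B, c(5L, 5L))),
                 "gene set")
})

# build a CorrelationMap directly from a rho matrix
mapFromRho <- function(rho, ua = "d0.r1", ub = "d0.r2", da = 0L, db = 0L) {
    dimnames(rho) <- list(as.character(seq_len(nrow(rho)) - 1L),
                          as.character(seq_len(ncol(rho)) - 1L))
    new("CorrelationMap", rho = rho, unitA = ua, unitB = ub,
        dayA = da, dayB = db,
        matching = data.frame(a = character(), b = character(),
                              rho = numeric()),
        unmatchedA = character(), unmatchedB = character())
}

test_that("reciprocal-best matching recovers permutations and flags strays", {
    # permutation: cluster i of A corresponds to sigma(i) of B
    rho <- matrix(0.1, 3, 3)
    rho[1, 2] <- 0.95; rho[2, 3] <- 0.9; rho[3, 1] <- 0.85
    res <- matchAndDiscard(list(mapFromRho(rho)), min_rho = 0.5)
    m <- matchedPairs(res$maps[[1]])
    expect_equal(nrow(m), 3)
    expect_equal(m$b[match(c("0", "1", "2"), m$a)], c("1", "2", "0"))
    expect_false(any(res$discard$discarded))

    # two mutual best pairs plus a third row whose best is non-reciprocal
    rho2 <- rbind(c(0.95, 0.10, 0.10),
                  c(0.10, 0.92, 0.10),
                  c(0.80, 0.10, 0.20))   # row 3 prefers col 1, taken by row 1
    res2 <- matchAndDiscard(list(mapFromRho(rho2)), min_rho = 0.5)
    m2 <- matchedPairs(res2$maps[[1]])
    expect_setequal(m2$a, c("0", "1"))
    expect_true("2" %in% unmatchedClusters(res2$maps[[1]])$a)
    d <- res2$discard
    expect_true(d$discarded[d$unit == "d0.r1" & d$cluster == "2"])
})

test_that("a low-correlation cluster is discarded, threshold respected", {
    rho <- diag(3) * 0.9 + 0.05
    rho <- rbind(rho, c(0.3, 0.2, 0.25))     # extra A-cluster below min_rho
    res <- matchAndDiscard(list(mapFromRho(rho)), min_rho = 0.5)
    d <- res$discard
    expect_equal(sum(d$discarded), 1)
    expect_true(d$discarded[d$unit == "d0.r1" & d$cluster == "3"])
    expect_error(matchAndDiscard(list()), "empty")
})

test_that("assignment backend agrees with reciprocal best on clean maps", {
    set.seed(30)
    rho <- matrix(runif(16, 0, 0.3), 4, 4)
    diag(rho) <- runif(4, 0.8, 0.99)
    perm <- sample(4)
    rho <- rho[, perm]
    r1 <- matchAndDiscard(list(mapFromRho(rho)), min_rho = 0.5)
    r2 <- matchAndDiscard(list(mapFromRho(rho)), min_rho = 0.5,
                          method = "assignment")
    m1 <- matchedPairs(r1$maps[[1]]); m2 <- matchedPairs(r2$maps[[1]])
    expect_equal(m1[order(m1$a), c("a", "b")], m2[order(m2$a), c("a", "b")],
                 ignore_attr = TRUE)
})

test_that("families are connected components with size-ordered labels", {
    # 3 units, same 2 clusters each, chained matches
    mk <- function(ua, ub, da, db) {
        rho <- matrix(c(0.9, 0.1, 0.1, 0.8), 2, 2)
        mapFromRho(rho, ua, ub, da, db)
    }
    maps <- list(mk("d0.r1", "d0.r2", 0L, 0L),
                 mk("d0.r1", "d3.r1", 0L, 3L),
                 mk("d0.r2", "d3.r1", 0L, 3L))
    res <- matchAndDiscard(maps, min_rho = 0.5)
    sizes <- list("d0.r1" = c("0" = 50L, "1" = 10L),
                  "d0.r2" = c("0" = 55L, "1" = 12L),
                  "d3.r1" = c("0" = 60L, "1" = 11L))
    fm <- consolidateFamilies(res, sizes = sizes)
    asg <- familyAssignments(fm)
    expect_equal(nrow(asg), 6)
    expect_setequal(as.character(asg$family), c("A", "B"))
    # cluster 0 (larger everywhere) must be family A
    expect_true(all(asg$family[asg$cluster == "0"] == "A"))
    expect_equal(nrow(discardedClusters(fm)), 0)
})

test_that("transitive chains merge into a single family", {
    # r1c1-r2c3 and r2c3-r3c2 chained via between-timepoint maps
    rho_ab <- matrix(0.05, 2, 4); rho_ab[1, 3] <- 0.9; rho_ab[2, 1] <- 0.85
    rho_bc <- matrix(0.05, 4, 3); rho_bc[3, 2] <- 0.88; rho_bc[1, 1] <- 0.8
    maps <- list(mapFromRho(rho_ab, "d0.r1", "d0.r2", 0L, 0L),
                 mapFromRho(rho_bc, "d0.r2", "d3.r1", 0L, 3L))
    res <- matchAndDiscard(maps, min_rho = 0.5, discard_fraction = 0)
    fm <- consolidateFamilies(res)
    asg <- as.data.frame(familyAssignments(fm))
    fam_of <- function(u, cl) asg$family[asg$unit == u & asg$cluster == cl]
    expect_equal(fam_of("d0.r1", "0"), fam_of("d0.r2", "2"))
    expect_equal(fam_of("d0.r2", "2"), fam_of("d3.r1", "1"))
})

test_that("conflicting components split along the weakest edge", {
    # r1c0-r2c0 (0.95) and r1c1-d3c0 (0.9) are strong; the weak
    # r2c0-d3c0 (0.6) edge fuses them into one component holding both
    # clusters of unit d0.r1 -> conflict, resolved by cutting the 0.6 edge
    m1 <- mapFromRho(rbind(c(0.95, 0.05), c(0.05, 0.10)),
                     "d0.r1", "d0.r2", 0L, 0L)
    m2 <- mapFromRho(rbind(c(0.05, 0.05), c(0.90, 0.05)),
                     "d0.r1", "d3.r1", 0L, 3L)
    m3 <- mapFromRho(rbind(c(0.60, 0.05), c(0.05, 0.05)),
                     "d0.r2", "d3.r1", 0L, 3L)
    res <- matchAndDiscard(list(m1, m2, m3), min_rho = 0.4,
                           discard_fraction = 0)
    expect_warning(fm <- consolidateFamilies(res), "split")
    asg <- as.data.frame(familyAssignments(fm))
    # within-unit clusters must land in different families
    for (u in unique(asg$unit)) {
        fams <- asg$family[asg$unit == u]
        expect_equal(anyDuplicated(fams), 0)
    }
    fam_of <- function(u, cl) asg$family[asg$unit == u & asg$cluster == cl]
    expect_equal(fam_of("d0.r1", "0"), fam_of("d0.r2", "0"))
    expect_equal(fam_of("d0.r1", "1"), fam_of("d3.r1", "0"))
})

test_that("pooling centers batches exactly and validates labels", {
    set.seed(40)
    genes <- sprintf("g%d", 1:20)
    a <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(genes, sprintf("a%02d", 1:15)))
    offset <- rnorm(20)
    b <- a + offset            # constant per-gene batch offset
    colnames(b) <- sprintf("b%02d", 1:15)
    merged <- poolAndCorrect(list(a, b), batch = c("b1", "b2"))
    corr <- SummarizedExperiment::assay(merged, "corrected")
    bm1 <- rowMeans(corr[, merged$batch == "b1"])
    bm2 <- rowMeans(corr[, merged$batch == "b2"])
    expect_equal(bm1, bm2, tolerance = 1e-12)
    # single batch: corrected equals input
    single <- poolAndCorrect(list(a), batch = "b1")
    expect_equal(SummarizedExperiment::assay(single, "corrected"),
                 SummarizedExperiment::assay(single, "logcounts"))
    expect_error(poolAndCorrect(list(a, b), batch = rep("x", 7)),
                 "length")
    # a 1-cell batch is excluded with a warning
    tiny <- a[, 1, drop = FALSE]; colnames(tiny) <- "t1"
    expect_warning(p <- poolAndCorrect(list(a, tiny), c("big", "tiny")),
                   "fewer than 2")
    expect_false("tiny" %in% unique(p$batch))
})

test_that("diagonal dominance counts strict row maxima", {
    rho <- diag(4) * 0.9 + 0.05
    m <- mapFromRho(rho)
    res <- matchAndDiscard(list(m), min_rho = 0.5)
    dd <- diagonalDominance(res$maps[[1]])
    expect_equal(dd$dominance, 1.0)
    # force the identity matching; one row's max is off the match
    rho2 <- rho; rho2[2, 4] <- 0.99
    m2 <- mapFromRho(rho2)
    ident <- data.frame(a = as.character(0:3), b = as.character(0:3))
    dd2 <- diagonalDominance(m2, matching = ident)
    expect_equal(dd2$dominance, 0.75)
    expect_equal(dd2$rows$off_which[dd2$rows$a == "1"], "3")
    expect_error(diagonalDominance(m), "empty matching")
})

test_that("final clustering assigns families by plurality, stable relabeling", {
    set.seed(50)
    genes <- sprintf("g%d", 1:30)
    prof <- list(A = rnorm(30, 2), B = rnorm(30, -1))
    cells <- cbind(matrix(prof$A, 30, 40), matrix(prof$B, 30, 35))
    rownames(cells) <- genes
    colnames(cells) <- sprintf("c%03d", 1:75)
    merged <- poolAndCorrect(list(cells), batch = "b1")
    merged$family <- rep(c("A", "B"), c(40, 35))
    merged$unit <- rep(c("d0.r1", "d0.r2"), length.out = 75)
    fin <- suppressWarnings(finalCluster(merged, k = 2, n_hvg = 30,
                                         n_components = 2, seed = 1))
    expect_setequal(unique(fin$family), c("A", "B"))
    expect_equal(unname(table(fin$family)["A"]), 40,  ignore_attr = TRUE)
    # contribution table rows sum to cluster sizes
    expect_equal(unname(rowSums(fin$contribution)),
                 as.vector(table(fin$labels)))
})
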