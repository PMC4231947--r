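test_that("oligotype correlations: self-diagonal 1, scale invariant, honest NA", {
    tabs <- exampleTables()
    cc <- otCorrelations(tabs$med, tabs$med)
    expect_equal(unname(diag(cc)), rep(1, 3))

    cts <- otCounts(tabs$med)
    doubled <- otTable(cts * 2L)
    expect_equal(unname(diag(otCorrelations(tabs$med, doubled))),
        rep(1, 3))

    # antithetic hand example
    a <- otTable(matrix(c(1L, 2L, 3L), 3, 1,
        dimnames = list(paste0("S", 1:3), "X")))
    b <- otTable(matrix(c(3L, 2L, 1L), 3, 1,
        dimnames = list(paste0("S", 1:3), "Y")))
    expect_equal(unname(otCorrelations(a, b)[1, 1]), -1)

    # a constant column has no defined correlation: NA, never 0
    konst <- otTable(matrix(c(1L, 2L, 3L, 5L, 5L, 5L), 3, 2,
        dimnames = list(paste0("S", 1:3), c("V", "K"))))
    cc2 <- otCorrelations(konst, konst)
    expect_true(all(is.na(cc2["K", ])))
    expect_equal(cc2["V", "V"], 1)

    bad <- otTable(matrix(1L, 2, 1,
        dimnames = list(c("T1", "T2"), "X")))
    expect_error(otCorrelations(a, bad), "different sample sets")
})

test_that("RV coefficient: identity, invariances, published value", {
    tabs <- exampleTables()
    expect_equal(rvCoefficient(tabs$med, tabs$med), 1)
    # centering + global scale invariance
    shifted <- otTable(otCounts(tabs$med) * 2L + 7L)
    expect_equal(rvCoefficient(tabs$med, shifted), 1)
    expect_equal(rvCoefficient(tabs$med, tabs$op), 0.9824,
        tolerance = 0.001 / 0.9824)
    # row order of the second table must not matter
    reord <- otTable(otCounts(tabs$op)[13:1, ])
    expect_equal(rvCoefficient(tabs$med, reord),
        rvCoefficient(tabs$med, tabs$op))
    konst <- otTable(matrix(5L, 13, 2, dimnames =
        list(sampleNames(tabs$med), c("A", "B"))))
    expect_error(rvCoefficient(tabs$med, konst), "undefined")
})

test_that("dissimilarities match their closed forms", {
    t <- otTable(matrix(c(1L, 0L, 2L, 0L, 1L, 2L), 3, 2,
        dimnames = list(c("S1", "S2", "S3"), c("A", "B"))))
    bc <- as.matrix(dissimilarity(t, "bray_curtis"))
    expect_equal(bc["S1", "S2"], 1)        # disjoint oligotypes
    expect_equal(bc["S3", "S3"], 0)
    eu <- as.matrix(dissimilarity(t, "euclidean"))
    expect_equal(eu["S1", "S2"], sqrt(2))
    # [2,2] vs [1,1] -> BC = 2/6
    t2 <- otTable(matrix(c(2L, 1L, 2L, 1L), 2, 2,
        dimnames = list(c("S1", "S2"), c("A", "B"))))
    expect_equal(as.matrix(dissimilarity(t2, "bray_curtis"))["S1", "S2"],
        1 / 3)
    expect_true(all(as.matrix(dissimilarity(t, "bray_curtis")) <= 1))
    # a pair of empty samples is defined as 0, not NaN
    t3 <- otTable(matrix(c(0L, 0L, 1L), 3, 1,
        dimnames = list(c("S1", "S2", "S3"), "A")))
    expect_equal(as.matrix(dissimilarity(t3, "bray_curtis"))["S1", "S2"],
        0)
})

test_that("Mantel test: self-comparison, relabelling invariance, seeding", {
    tabs <- exampleTables()
    d1 <- dissimilarity(tabs$med, "bray_curtis")
    d2 <- dissimilarity(tabs$op, "bray_curtis")
    self <- mantelTest(d1, d1, nPerm = 99, seed = 3)
    expect_equal(self$r, 1)
    m1 <- mantelTest(d1, d2, nPerm = 199, seed = 3)
    expect_identical(m1, mantelTest(d1, d2, nPerm = 199, seed = 3))
    expect_gt(m1$p, 0)
    expect_lte(m1$p, 1)
    # consistent relabelling of both matrices leaves r unchanged
    perm <- c(4:13, 1:3)
    t1p <- otTable(otCounts(tabs$med)[perm, ])
    t2p <- otTable(otCounts(tabs$op)[perm, ])
    m2 <- mantelTest(dissimilarity(t1p, "bray_curtis"),
        dissimilarity(t2p, "bray_curtis"), nPerm = 99, seed = 3)
    expect_equal(m2$r, m1$r)
    small <- stats::dist(matrix(1:4, 2, 2))
    expect_error(mantelTest(small, small, 99, 1), ">= 3 samples")
})

test_that("correspondence analysis follows the chi-square SVD geometry", {
    # perfect 2x2 association: one axis, inertia 1
    block <- otTable(matrix(c(5L, 0L, 0L, 5L), 2, 2,
        dimnames = list(c("S1", "S2"), c("A", "B"))))
    ord <- correspondenceAnalysis(block)
    expect_length(ord@inertia, 1)
    expect_equal(unname(ord@inertia), 1)
    # independence model: rank 0
    flat <- otTable(matrix(c(1L, 1L, 1L, 1L), 2, 2,
        dimnames = list(c("S1", "S2"), c("A", "B"))))
    expect_error(correspondenceAnalysis(flat), "no inertia")
    # empty rows/columns are dropped with a warning
    cts <- matrix(c(5L, 0L, 2L, 0L, 0L, 0L, 1L, 0L, 7L), 3, 3,
        dimnames = list(paste0("S", 1:3), c("A", "B", "C")))
    expect_warning(correspondenceAnalysis(otTable(cts)), "empty")
})

test_that("CA satisfies the transition formula on random tables", {
    set.seed(51)
    for (i in 1:3) {
        cts <- matrix(rpois(7 * 5, 10) + 1L, 7, 5,
            dimnames = list(paste0("S", 1:7), paste0("OT", 1:5)))
        t <- otTable(cts)
        ord <- correspondenceAnalysis(t)
        # row principal coords are mass-weighted barycenters of column
        # standard coords: F = D_r^{-1} P Gamma
        P <- cts[, otLabels(t)] / sum(cts)
        bary <- sweep(P %*% ord@colStandard, 1, rowSums(P), "/")
        expect_equal(unname(ord@rowPrincipal), unname(bary),
            tolerance = 1e-10)
        # standard * singular value = principal
        expect_equal(ord@rowStandard %*% diag(sqrt(ord@inertia)),
            ord@rowPrincipal, ignore_attr = TRUE)
    }
})

test_that("CA of the published tables yields valid 2D representations", {
    tabs <- exampleTables()
    expect_length(correspondenceAnalysis(tabs$med)@inertia, 2)
    expect_length(correspondenceAnalysis(tabs$op)@inertia, 2)
})

test_that("Procrustes correlation: rotation invariance and reflection", {
    tabs <- exampleTables()
    ord <- correspondenceAnalysis(tabs$med)
    # rotated, uniformly scaled copy of itself: r = 1
    theta <- 0.7
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    rot <- ord
    rot@rowStandard <- ord@rowStandard %*% R * 3
    rot@rowPrincipal <- ord@rowPrincipal %*% R * 3
    expect_equal(procrustesCorr(ord, rot, 2, 99, 1)$r, 1)
    # reflections are in the orthogonal group
    refl <- ord
    refl@rowStandard <- ord@rowStandard %*% diag(c(-1, 1))
    refl@rowPrincipal <- ord@rowPrincipal %*% diag(c(-1, 1))
    expect_equal(procrustesCorr(ord, refl, 2, 99, 1)$r, 1)
    expect_error(procrustesCorr(ord, ord, nAxes = 5), "at least 5 axes")
})

test_that("comparison report reproduces the published summary", {
    tabs <- exampleTables()
    rep <- compareTables(tabs$med, tabs$op, nPerm = 199, seed = 2)
    expect_equal(unname(unlist(rep$total_variance)),
        c(472.1, 953.3), tolerance = 0.0005)
    expect_equal(rep$rv, 0.9824, tolerance = 0.001)
    expect_equal(rep$mantel_bray$r, 0.987, tolerance = 0.001)
    expect_equal(rep$mantel_euclidean$r, 0.975, tolerance = 0.001)
    expect_equal(rep$procrustes$r, 0.879, tolerance = 0.005)
    # self-comparison: all agreement statistics hit 1
    self <- compareTables(tabs$med, tabs$med, nPerm = 99, seed = 2)
    expect_equal(self$rv, 1)
    expect_equal(self$mantel_bray$r, 1)
    expect_equal(self$procrustes$r, 1)
})
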