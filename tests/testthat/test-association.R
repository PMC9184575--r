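test_that("the quantile caller finds, merges and filters signal blocks", {
    # one rectangular block of width 400 above background
    dens <- numeric(50000)
    dens[10001:10400] <- 5
    tr <- densityTrack(dens, binSize = 50)
    pk <- callPeaksSimple(tr, thresholdQuantile = 0.95,
                          minWidth = 200, mergeGap = 150)
    expect_length(pk, 1)
    expect_equal(c(start(pk) - 1, end(pk)), c(10000, 10400))
    expect_equal(pk$score, 5)

    # two blocks separated by 100 bp < mergeGap are merged
    dens2 <- numeric(50000)
    dens2[10001:10300] <- 5
    dens2[10401:10700] <- 5
    pk2 <- callPeaksSimple(densityTrack(dens2, 50), 0.95, 200, 150)
    expect_length(pk2, 1)
    expect_equal(c(start(pk2) - 1, end(pk2)), c(10000, 10700))

    # runs shorter than minWidth are dropped
    dens3 <- numeric(50000)
    dens3[10001:10100] <- 5
    expect_length(callPeaksSimple(densityTrack(dens3, 50), 0.95,
                                  200, 150), 0)

    # all-zero track: empty peak set, not an error
    expect_length(callPeaksSimple(densityTrack(numeric(5000), 50)), 0)
})

test_that("peak calling is idempotent on its own indicator signal", {
    dens <- numeric(50000)
    dens[c(5001:5600, 20001:20450, 40001:40250)] <- 1
    tr <- densityTrack(dens, binSize = 50)
    pk1 <- callPeaksSimple(tr, 0.5, 200, 150)
    ind <- numeric(50000)
    for (i in seq_along(pk1)) ind[start(pk1)[i]:end(pk1)[i]] <- 1
    pk2 <- callPeaksSimple(densityTrack(ind, 50), 0.5, 200, 150)
    expect_equal(granges(pk2), granges(pk1))
})

test_that("peaks from a promoter-peaked simulation contain the TSSs", {
    arch <- signalArchitecture(promoterWeight = 0.6,
                               bodyGradientWeight = 0,
                               spikeinFraction = 0.1)
    g <- simulateGenome(nGenes = 40, chromLength = 1e6, seed = 53)
    fs <- simulateFragments(g$genes, g$chromSizes, g$chromClass, arch,
                            3e5, seed = 54)
    pk <- callPeaksSimple(normalizedCoverage(fs), 0.97, 200, 150)
    expect_gt(length(pk), 10)
    tss <- GRanges("chr1", IRanges(unname(tssPositions(g$genes)) + 1,
                                   width = 1))
    hasTss <- mean(overlapsAny(pk, tss, maxgap = 100))
    expect_gte(hasTss, 0.9)
})

test_that("Fisher overlap p-values equal hypergeometric enumeration", {
    ft <- fisherExactTable(3, 1, 1, 3)
    expect_equal(ft$pValue, enumFisherP(3, 1, 1, 3), tolerance = 1e-12)
    # spot-check a grid of tables
    set.seed(59)
    for (i in 1:40) {
        cells <- sample(0:12, 4, TRUE)
        if (sum(cells) == 0) next
        expect_equal(
            fisherExactTable(cells[1], cells[2], cells[3],
                             cells[4])$pValue,
            enumFisherP(cells[1], cells[2], cells[3], cells[4]),
            tolerance = 1e-9)
    }
})

test_that("overlapTest builds the right table over a universe", {
    universe <- GRanges("chr1", IRanges(seq(1, 10000, by = 1000),
                                        width = 500))
    a <- universe[c(1, 2, 3, 4)]
    b <- universe[c(3, 4, 5, 6)]
    res <- overlapTest(a, b, universe)
    expect_equal(res@nOverlap, 2L)
    expect_equal(unname(res@table[1, ]), c(2, 2))
    expect_equal(res@pValue, enumFisherP(2, 2, 2, 4),
                 tolerance = 1e-9)
    # maximal overlap is at least as significant as any disjoint split
    same <- overlapTest(a, a, universe)
    expect_equal(same@nOverlap, 4L)
    disjoint <- overlapTest(universe[1:4], universe[5:8], universe)
    expect_lte(same@pValue, disjoint@pValue)
    expect_lt(disjoint@oddsRatio, 1)
    expect_error(overlapTest(a, b, GRanges()), "empty universe")
})

test_that("promoter signal tables match brute-force region means", {
    fix <- tinyGenome()
    set.seed(61)
    s0 <- sample(0:49000, 600, TRUE)
    fs <- makeFragments(rep("chr1", 600), s0, s0 + 120,
                        fix$chromSizes, fix$chromClass)
    trA <- normalizeTrack(fragmentsToCoverage(fs, 50), 1)
    trB <- normalizeTrack(fragmentsToCoverage(fs, 50), 2.5)
    prom <- promoterRegions(fix$genes)
    tab <- promoterSignalTable(list(A = trA, B = trB), prom)
    expect_equal(dim(tab), c(2, 2))
    densA <- trackPerBaseDensity(trA, "chr1")
    want <- vapply(seq_along(prom), function(i)
        perBaseRegionMean(densA, start(prom)[i] - 1, end(prom)[i]),
        numeric(1))
    expect_equal(unname(tab[, "A"]), want, tolerance = 1e-9)
    expect_equal(unname(tab[, "B"]), 2.5 * want, tolerance = 1e-9)

    # uniform track: every cell equals the density
    trU <- densityTrack(rep(4, 50000), 50)
    expect_true(all(abs(promoterSignalTable(list(u = trU), prom) - 4)
                    < 1e-9))

    # restriction to peaks covering one promoter halves the rows
    pkCover <- GRanges("chr1", IRanges(9800, 10300))
    tab2 <- promoterSignalTable(list(A = trA), prom,
                                restrictTo = pkCover)
    expect_equal(nrow(tab2), 1)
    expect_error(promoterSignalTable(list(A = trA), prom,
                                     restrictTo = GRanges("chr1",
                                         IRanges(1, 2))),
                 "no promoters")
})

test_that("Pearson correlation and the linear fit behave", {
    r <- correlateSignals(c(1, 2, 3), c(2, 4, 6))
    expect_equal(r@r, 1.0)
    expect_equal(r@slope, 2.0)
    expect_equal(r@intercept, 0.0)
    expect_equal(correlateSignals(1:10, -(1:10))@r, -1.0)
    set.seed(67)
    n <- 2000; rho <- 0.5
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_equal(correlateSignals(x, y)@r, rho, tolerance = 0.05)
    expect_error(correlateSignals(rep(1, 5), 1:5), "zero variance")
    expect_error(correlateSignals(setNames(1:3, c("a", "b", "c")),
                                  setNames(1:3, c("a", "b", "d"))),
                 "misaligned")
})

test_that("delta-vs-occupancy recovers injected slopes and their order", {
    expect_error(deltaVsOccupancy(rep(0, 10), rnorm(10)),
                 "zero variance")
    set.seed(71)
    recovered <- vapply(1:20, function(s) {
        set.seed(s)
        occ <- runif(200, 0, 10)
        delta <- 0.8 * occ + rnorm(200, 0, 1)
        fit <- deltaVsOccupancy(delta, occ)
        se <- sqrt((1 - fit@r^2) / (fit@n - 2)) * sd(delta) / sd(occ)
        expect_lt(abs(fit@slope - 0.8), 3 * se)
        fit@slope
    }, numeric(1))
    expect_equal(mean(recovered), 0.8, tolerance = 0.05)
    # full-length vs truncated rescue: slope ordering preserved
    set.seed(73)
    occ <- runif(300, 0, 10)
    full <- deltaVsOccupancy(1.0 * occ + rnorm(300, 0, 1), occ)
    trunc <- deltaVsOccupancy(0.4 * occ + rnorm(300, 0, 1), occ)
    expect_gt(full@slope, trunc@slope)
    expect_gt(full@r, 0.5)
})
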