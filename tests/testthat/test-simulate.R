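test_that("genome simulation is reproducible, stranded and bounded", {
    g1 <- simulateGenome(nGenes = 50, chromLength = 5e5, seed = 89)
    g2 <- simulateGenome(nGenes = 50, chromLength = 5e5, seed = 89)
    expect_identical(g1$genes, g2$genes)
    expect_true(all(start(g1$genes) >= 1))
    expect_true(all(end(g1$genes) <= 5e5))
    # non-overlapping placement
    expect_equal(length(reduce(granges(g1$genes), min.gapwidth = 0L)),
                 length(g1$genes))

    single <- simulateGenome(nGenes = 1, chromLength = 5e4, seed = 1)
    expect_length(single$genes, 1)

    big <- simulateGenome(nGenes = 1000, chromLength = 1.2e7, seed = 2,
                          minLen = 2000, maxLen = 8000)
    frac <- mean(as.character(strand(big$genes)) == "+")
    expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 1000))

    expect_error(simulateGenome(nGenes = 100, chromLength = 1e5,
                                minLen = 5000, maxLen = 5000, seed = 3),
                 "infeasible")
})

test_that("fragment simulation is reproducible and respects the mixture", {
    g <- simulateGenome(nGenes = 100, chromLength = 1e6, seed = 97)
    arch <- signalArchitecture()
    f1 <- simulateFragments(g$genes, g$chromSizes, g$chromClass, arch,
                            5e4, seed = 101)
    f2 <- simulateFragments(g$genes, g$chromSizes, g$chromClass, arch,
                            5e4, seed = 101)
    expect_identical(fragments(f1), fragments(f2))

    # spike-in fraction close to its nominal value
    counts <- countByRefClass(f1)
    expect_lt(abs(counts[["spikein"]] / 5e4 - 0.1),
              4 * sqrt(0.1 * 0.9 / 5e4))

    # empirical promoter-window mass converges to the analytic
    # expectation of the architecture (within 2% at 1e6 fragments)
    fBig <- simulateFragments(g$genes, g$chromSizes, g$chromClass,
                              arch, 1e6, seed = 103)
    tr <- fragmentsToCoverage(fBig, 50)
    exp <- expectedCoverage(g$genes, g$chromSizes, g$chromClass, arch,
                            binSize = 50)
    prom <- promoterRegions(g$genes)
    inProm <- function(track) {
        tot <- sum(binValues(track)$chr1)
        sum(regionMeanSignal(track, prom) * width(prom)) / tot
    }
    expect_lt(abs(inProm(tr) - inProm(exp)), 0.02)
})

test_that("null, gradient-only and promoter-only architectures shape the index", {
    g <- simulateGenome(nGenes = 100, chromLength = 1e6, seed = 107)
    null <- signalArchitecture(promoterWeight = 0,
                               bodyGradientWeight = 0)
    fs <- simulateFragments(g$genes, g$chromSizes, g$chromClass, null,
                            2e5, seed = 109)
    idx <- h3k36me3Index(normalizedCoverage(fs), g$genes)
    expect_equal(indexValue(idx), 1.0, tolerance = 0.05)

    # gradient-only: sampled metagene body rises 5'->3'
    grad <- signalArchitecture(promoterWeight = 0,
                               bodyGradientWeight = 0.8)
    fg <- simulateFragments(g$genes, g$chromSizes, g$chromClass, grad,
                            4e5, seed = 113)
    m <- buildMetageneMatrix(normalizedCoverage(fg), g$genes,
                             flankBp = 2000, bodyBins = 60)
    body <- averageProfile(m)[41:100]
    expect_gt(mean(body[41:60]), mean(body[1:20]))

    # doubling the promoter weight strictly increases the index
    lo <- signalArchitecture(promoterWeight = 0.15)
    hi <- signalArchitecture(promoterWeight = 0.30)
    iLo <- h3k36me3Index(normalizedCoverage(
        simulateFragments(g$genes, g$chromSizes, g$chromClass, lo,
                          2e5, seed = 127)), g$genes)
    iHi <- h3k36me3Index(normalizedCoverage(
        simulateFragments(g$genes, g$chromSizes, g$chromClass, hi,
                          2e5, seed = 127)), g$genes)
    expect_gt(indexValue(iHi), indexValue(iLo))
})

test_that("KO panels pair every knockout with a same-batch wild type", {
    g <- simulateGenome(nGenes = 40, chromLength = 4e5, seed = 131)
    eff <- setNames(c(0.7, 1, 1, 1, 0.7, 1), paste0("ko", 1:6))
    design <- panelDesign(eff, baseDepth = 1e4, batchSize = 3L,
                          depthMultipliers = c(1, 2))
    panel <- simulateKoPanel(design, signalArchitecture(), g$genes,
                             g$chromSizes, g$chromClass, seed = 137)
    mf <- panel$manifest
    expect_equal(nrow(mf), 8)  # 6 KO + 2 WT
    for (b in unique(mf$batch))
        expect_equal(sum(mf$role == "WT" & mf$batch == b), 1)
    expect_equal(panel$truth$effect, unname(eff))
    # batch depth multipliers applied
    d1 <- length(panel$fragments[[mf$sample_id[mf$batch ==
                                               unique(mf$batch)[1]][1]]])
    d2 <- length(panel$fragments[[mf$sample_id[mf$batch ==
                                               unique(mf$batch)[2]][1]]])
    expect_equal(d2 / d1, 2, tolerance = 0.01)
})

test_that("expression counts are reproducible with injected truth", {
    ids <- paste0("g", 1:50)
    lens <- setNames(rep(2000, 50), ids)
    e1 <- simulateExpression(ids, seed = 139, lengths = lens,
                             log2fc = c(g7 = 2))
    e2 <- simulateExpression(ids, seed = 139, lengths = lens,
                             log2fc = c(g7 = 2))
    expect_identical(e1$wt, e2$wt)
    expect_identical(e1$ko, e2$ko)
    expect_equal(unname(e1$log2fc["g7"]), 2)
    expect_gt(mean(e1$ko["g7", ]) / mean(e1$wt["g7", ]), 2)
})
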