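fix <- tinyGenome()

test_that("index is exactly 1 on uniform coverage and ratios on steps", {
    tr <- densityTrack(rep(3, 50000), binSize = 50)
    idx <- h3k36me3Index(tr, fix$genes)
    expect_equal(indexValue(idx), 1.0)
    expect_equal(idx@nGenes, 2L)

    # promoter density 4, body density 2 (gene coords align to 50 bp
    # bins so the step profile is represented exactly)
    dens <- rep(2, 50000)
    for (g in seq_along(fix$genes)) {
        tss0 <- unname(tssPositions(fix$genes))[g]
        dens[(tss0 - 500 + 1):(tss0 + 500)] <- 4
    }
    tr2 <- densityTrack(dens, binSize = 50)
    expect_equal(indexValue(h3k36me3Index(tr2, fix$genes)), 2.0,
                 tolerance = 1e-9)
})

test_that("index matches the per-base brute-force oracle on 5 genes", {
    set.seed(37)
    chromSizes <- c(chr1 = 120000, spike = 5000)
    starts0 <- c(10000, 35000, 60000, 80000, 100000)
    lens <- c(8000, 6000, 9000, 5000, 7000)
    strands <- c("+", "-", "+", "-", "+")
    genes <- GRanges(factor(rep("chr1", 5),
                            levels = names(chromSizes)),
                     IRanges(starts0 + 1, starts0 + lens),
                     strand = strands)
    names(genes) <- paste0("g", 1:5)
    seqlengths(genes) <- chromSizes
    s0 <- sample(0:119000, 3000, TRUE)
    fs <- makeFragments(rep("chr1", 3000), s0, s0 + 160, chromSizes,
                        c(chr1 = "sample", spike = "spikein"))
    tr <- normalizeTrack(fragmentsToCoverage(fs, 50), 1.25)
    got <- h3k36me3Index(tr, genes)

    dens <- trackPerBaseDensity(tr, "chr1")
    tss0 <- ifelse(strands == "-", starts0 + lens, starts0)
    tes0 <- ifelse(strands == "-", starts0, starts0 + lens)
    promMeans <- vapply(1:5, function(i)
        perBaseRegionMean(dens, tss0[i] - 500, tss0[i] + 500),
        numeric(1))
    bodyMeans <- vapply(1:5, function(i) {
        if (strands[i] == "-")
            perBaseRegionMean(dens, tes0[i], tss0[i] - 500)
        else perBaseRegionMean(dens, tss0[i] + 500, tes0[i])
    }, numeric(1))
    expect_equal(got@promoterSignal, mean(promMeans), tolerance = 1e-9)
    expect_equal(got@genebodySignal, mean(bodyMeans), tolerance = 1e-9)
    expect_equal(indexValue(got), mean(promMeans) / mean(bodyMeans),
                 tolerance = 1e-9)
    # per-gene aggregation variant
    perGene <- h3k36me3Index(tr, genes, aggregate = "perGene")
    expect_equal(indexValue(perGene), mean(promMeans / bodyMeans),
                 tolerance = 1e-9)
})

test_that("batch normalization divides KO by same-batch WT", {
    mk <- function(i, b) new("IndexResult", sampleId = "s",
                             promoterSignal = 1, genebodySignal = 1,
                             index = i, nGenes = 5L, batch = b)
    expect_equal(batchNormalize(mk(1.2, "b1"), mk(1.2, "b1")), 1.0)
    expect_equal(batchNormalize(mk(0.8, "b1"), mk(1.0, "b1")), 0.8)
    expect_error(batchNormalize(mk(1, "b1"), mk(1, "b2")), "mismatch")
})

test_that("the 15% criterion has closed unchanged boundaries and is monotone", {
    expect_equal(classifyChange(c(0.84, 0.85, 1.15, 1.16)),
                 c("decreased", "unchanged", "unchanged", "increased"))
    set.seed(41)
    r <- sort(runif(200, 0.5, 1.5))
    calls <- classifyChange(r)
    lev <- match(calls, c("decreased", "unchanged", "increased"))
    expect_true(all(diff(lev) >= 0))
    expect_error(classifyChange(-0.1), "> 0")
})

test_that("two-round confirmation requires agreeing non-null calls", {
    r1 <- data.frame(gene = c("a", "b", "c", "d"),
                     call = c("decreased", "decreased", "increased",
                              "unchanged"))
    r2 <- data.frame(gene = c("a", "b", "c"),
                     call = c("decreased", "unchanged", "increased"))
    h <- confirmHits(r1, r2)
    expect_equal(h$confirmed,
                 c("hit_decreased", "not_confirmed", "hit_increased",
                   "not_confirmed"))
    expect_error(confirmHits(r1, data.frame(gene = "z",
                                            call = "decreased")),
                 "not round 1")
})

test_that("a 30% promoter-only reduction produces a ~0.7 index ratio", {
    # promoter-dominated architecture so that background and gradient
    # contributions at promoters are small relative to the injected
    # effect
    arch <- signalArchitecture(promoterWeight = 0.5,
                               bodyGradientWeight = 0.45,
                               spikeinFraction = 0.1)
    g <- simulateGenome(nGenes = 100, chromLength = 1.5e6, seed = 43)
    wt <- simulateFragments(g$genes, g$chromSizes, g$chromClass, arch,
                            2e5, seed = 44)
    koArch <- promScreen:::.koArchitecture(arch, 0.7)
    ko <- simulateFragments(g$genes, g$chromSizes, g$chromClass,
                            koArch, 2e5, seed = 45)
    iWT <- h3k36me3Index(normalizedCoverage(wt), g$genes)
    iKO <- h3k36me3Index(normalizedCoverage(ko), g$genes)
    expect_equal(batchNormalize(iKO, iWT), 0.7, tolerance = 0.07)
})

test_that("screenRound ties KO calls to their batch WT", {
    g <- simulateGenome(nGenes = 60, chromLength = 8e5, seed = 47)
    eff <- c(koA = 0.7, koB = 1.0)
    design <- panelDesign(eff, baseDepth = 4e4, batchSize = 2L,
                          depthMultipliers = 1)
    panel <- simulateKoPanel(design, signalArchitecture(), g$genes,
                             g$chromSizes, g$chromClass, seed = 48)
    res <- screenRound(panel$fragments, panel$manifest, g$genes)
    expect_setequal(res$calls$gene, c("koA", "koB"))
    expect_equal(res$calls$call[res$calls$gene == "koA"], "decreased")
    expect_equal(res$calls$call[res$calls$gene == "koB"], "unchanged")
    expect_true(all(res$indices$n_genes > 0))
})
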