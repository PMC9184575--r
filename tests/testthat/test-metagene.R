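fix <- tinyGenome()

test_that("uniform signal yields uniform cells and a flat profile", {
    dens <- rep(2.5, 50000)
    tr <- densityTrack(dens, binSize = 50)
    m <- buildMetageneMatrix(tr, fix$genes, flankBp = 5000,
                             bodyBins = 100)
    expect_equal(ncol(metageneValues(m)), 2 * 100 + 100)
    expect_true(all(abs(metageneValues(m)[, 101:200] - 2.5) < 1e-9))
    prof <- averageProfile(m)
    # flanks of gA reach below position 10000-5000 = 5000 (in bounds),
    # so the full profile is flat over in-bounds columns
    expect_lt(max(prof[101:200]) - min(prof[101:200]), 1e-9)
})

test_that("a linear gradient over a + strand body gives increasing cells", {
    dens <- numeric(50000)
    dens[10001:15000] <- seq(1, 100, length.out = 5000)
    tr <- densityTrack(dens, binSize = 1)
    m <- buildMetageneMatrix(tr, fix$genes["gA"], flankBp = 1000,
                             bodyBins = 50)
    nf <- 1000  # track bin size is 1 bp
    body <- metageneValues(m)["gA", (nf + 1):(nf + 50)]
    expect_true(all(diff(body) > 0))
})

test_that("matrix equals the per-base brute-force oracle on a 2-gene fixture", {
    set.seed(23)
    s0 <- sample(0:49000, 800, TRUE)
    fs <- makeFragments(rep("chr1", 800), s0, s0 + 140,
                        fix$chromSizes, fix$chromClass)
    tr <- normalizeTrack(fragmentsToCoverage(fs, 50), 2.0)
    bodyBins <- 50  # gene lengths 5000 and 6000: both divisible by 50
    m <- buildMetageneMatrix(tr, fix$genes, flankBp = 2000,
                             bodyBins = bodyBins)
    dens <- trackPerBaseDensity(tr, "chr1")
    nf <- 2000 / 50
    oracleRow <- function(s0g, e0g, minus) {
        cellBounds <- if (!minus)
            c(seq(s0g - 2000, s0g, by = 50),
              s0g + (e0g - s0g) * seq_len(bodyBins - 1) / bodyBins,
              seq(e0g, e0g + 2000, by = 50))
        else
            c(seq(e0g + 2000, e0g, by = -50),
              e0g - (e0g - s0g) * seq_len(bodyBins - 1) / bodyBins,
              seq(s0g, s0g - 2000, by = -50))
        vapply(seq_len(length(cellBounds) - 1), function(i) {
            lo <- min(cellBounds[i], cellBounds[i + 1])
            hi <- max(cellBounds[i], cellBounds[i + 1])
            perBaseRegionMean(dens, lo, hi)
        }, numeric(1))
    }
    expect_equal(unname(metageneValues(m)["gA", ]),
                 oracleRow(10000, 15000, FALSE), tolerance = 1e-9)
    expect_equal(unname(metageneValues(m)["gB", ]),
                 oracleRow(30000, 36000, TRUE), tolerance = 1e-9)
})

test_that("mirrored minus-strand gene yields the identical row", {
    # signal pattern around a + gene, and its mirror image around a -
    # gene placed symmetrically on the same chromosome
    len <- 50000
    dens <- numeric(len)
    dens[10001:15000] <- seq_len(5000) / 100
    dens[8001:10000] <- 7
    mirror <- rev(dens)
    tr <- densityTrack(c(dens, mirror), binSize = 1, chrom = "chr1")
    gPlus <- GRanges("chr1", IRanges(10001, 15000), strand = "+")
    gMinus <- GRanges("chr1", IRanges(len + (len - 15000) + 1,
                                      len + (len - 10000)),
                      strand = "-")
    genes <- c(gPlus, gMinus)
    names(genes) <- c("p", "m")
    seqlengths(genes) <- c(chr1 = 2 * len)
    m <- buildMetageneMatrix(tr, genes, flankBp = 1000, bodyBins = 40)
    expect_equal(unname(metageneValues(m)["m", ]),
                 unname(metageneValues(m)["p", ]), tolerance = 1e-9)
})

test_that("average profiles equal naive column means", {
    mat <- matrix(runif(5 * 12), 5, 12,
                  dimnames = list(paste0("g", 1:5), NULL))
    m <- new("MetageneMatrix", values = mat, flankBp = 100L,
             binSize = 50L, bodyBins = 8L, excluded = character())
    expect_equal(unname(averageProfile(m)),
                 vapply(1:12, function(j) mean(mat[, j]), numeric(1)))
    expect_equal(unname(averageProfile(m, "g3")), unname(mat[3, ]))
    expect_error(averageProfile(m, character(0)), "empty")
    expect_error(averageProfile(m, "nope"), "not in matrix")
    two <- new("MetageneMatrix",
               values = matrix(c(0, 2), 2, 4,
                               dimnames = list(c("a", "b"), NULL)),
               flankBp = 50L, binSize = 50L, bodyBins = 2L,
               excluded = character())
    expect_equal(unname(averageProfile(two)), rep(1, 4))
})

test_that("expression quartile grouping follows the documented tie rule", {
    mat <- matrix(seq_len(8 * 6), 8, 6,
                  dimnames = list(paste0("g", 1:8), NULL))
    m <- new("MetageneMatrix", values = mat, flankBp = 50L,
             binSize = 50L, bodyBins = 4L, excluded = character())
    expr <- setNames(1:8, paste0("g", 1:8))
    gp <- groupedProfiles(m, expr)
    expect_setequal(names(gp$groups)[gp$groups == "high"],
                    c("g7", "g8"))
    expect_setequal(names(gp$groups)[gp$groups == "low"],
                    c("g1", "g2"))
    expect_equal(sum(gp$groups == "medium"), 4)
    # all-equal expression: stable gene-id order decides, sizes 2/4/2
    tied <- groupedProfiles(m, setNames(rep(5, 8), paste0("g", 1:8)))
    expect_equal(as.vector(table(tied$groups)[c("high", "medium", "low")]),
                 c(2, 4, 2))
    expect_setequal(names(tied$groups)[tied$groups == "low"],
                    c("g1", "g2"))
    expect_error(groupedProfiles(m, setNames(1:3, paste0("g", 1:3))),
                 "at least 4")
})

test_that("expression-correlated signal separates high and low profiles", {
    set.seed(31)
    n <- 40; ncol <- 30
    expr <- setNames(rexp(n), paste0("g", sprintf("%02d", 1:n)))
    bump <- dnorm(seq(-3, 3, length.out = ncol))
    mat <- t(vapply(names(expr), function(g)
        0.5 + expr[[g]] * bump + rnorm(ncol, 0, 0.01),
        numeric(ncol)))
    m <- new("MetageneMatrix", values = mat, flankBp = 250L,
             binSize = 50L, bodyBins = 20L, excluded = character())
    gp <- groupedProfiles(m, expr)
    mid <- 13:18
    expect_true(all(gp$high[mid] > gp$low[mid]))
})

test_that("metagene matrices round-trip through annotated TSV", {
    dens <- runif(50000)
    tr <- densityTrack(dens, binSize = 50)
    m <- buildMetageneMatrix(tr, fix$genes, flankBp = 1000,
                             bodyBins = 20)
    p <- tempfile(fileext = ".tsv")
    writeMetageneMatrix(m, p)
    m2 <- readMetageneMatrix(p)
    expect_equal(metageneValues(m2), metageneValues(m),
                 tolerance = 1e-9)
    expect_equal(m2@bodyBins, m@bodyBins)
})
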