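#' Simulate a compact genome of non-overlapping genes
#'
#' Places \code{nGenes} genes of uniform-random length on one sample
#' chromosome, separated by random gaps, with random strands, plus a
#' dedicated spike-in chromosome that carries no genes. Reproducible
#' under a fixed seed.
#'
#' @param nGenes number of genes (>= 1).
#' @param chromLength sample chromosome length in bases.
#' @param minLen,maxLen gene length bounds.
#' @param spikeinLength spike-in chromosome length.
#' @param seed optional integer seed (sets the RNG).
#' @param chrom,spikeinChrom chromosome names.
#' @return list with \code{genes} (named GRanges), \code{chromSizes}
#'   (named numeric) and \code{chromClass} (named character).
#' @examples
#' g <- simulateGenome(nGenes = 5, chromLength = 1e5, seed = 1)
#' length(g$genes)
#' @export
simulateGenome <- function(nGenes = 150L, chromLength = 2e6,
                           minLen = 2000L, maxLen = 8000L,
                           spikeinLength = 20000L, seed = NULL,
                           chrom = "chr1", spikeinChrom = "spikein") {
    if (nGenes < 1) stop("nGenes must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    lens <- sample(seq.int(minLen, maxLen), nGenes, replace = TRUE)
    gapTotal <- chromLength - sum(lens)
    if (gapTotal < nGenes + 1)
        stop("infeasible packing: genes do not fit on the chromosome")
    w <- diff(c(0, sort(runif(nGenes)), 1))
    gaps <- floor(w * gapTotal)
    starts0 <- cumsum(gaps[seq_len(nGenes)]) +
        c(0, cumsum(lens[seq_len(nGenes - 1)]))
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)
    chromSizes <- setNames(c(chromLength, spikeinLength),
                           c(chrom, spikeinChrom))
    genes <- GRanges(factor(rep(chrom, nGenes),
                            levels = names(chromSizes)),
                     IRanges(starts0 + 1, starts0 + lens),
                     strand = strands)
    names(genes) <- sprintf("g%04d", seq_len(nGenes))
    seqlengths(genes) <- chromSizes
    list(genes = genes, chromSizes = chromSizes,
         chromClass = setNames(c("sample", "spikein"),
                               c(chrom, spikeinChrom)))
}

# Inverse CDF of the gene-body gradient density f(t) ~ 1 + s*t on [0,1].
.gradientQuantile <- function(u, s) {
    if (s == 0) return(u)
    (sqrt(1 + s * (2 + s) * u) - 1) / s
}

#' Simulate CUT&Tag-like fragments under a signal architecture
#'
#' Each fragment is drawn from the mixture defined by the architecture:
#' with probability \code{spikeinFraction} it is placed uniformly on the
#' spike-in chromosome; otherwise its midpoint comes from the uniform
#' background, from Normal(TSS, sigmaProm) at a uniformly chosen gene,
#' or from the 5'->3' rising gradient over a uniformly chosen gene
#' body. Lengths are Normal(fragLenMean, fragLenSd) clipped at 50 bp;
#' fragments are clipped to chromosome bounds.
#'
#' @param genes named GRanges of gene models.
#' @param chromSizes named chromosome lengths (sample + spike-in).
#' @param chromClass named chromosome -> class map.
#' @param arch a \linkS4class{SignalArchitecture}.
#' @param nFragments number of fragments to draw.
#' @param seed optional integer seed.
#' @param sampleId identifier for the set.
#' @return A \linkS4class{FragmentSet}.
#' @export
simulateFragments <- function(genes, chromSizes, chromClass, arch,
                              nFragments, seed = NULL,
                              sampleId = "sim") {
    if (nFragments < 1) stop("nFragments must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    n <- as.integer(nFragments)
    sampleChroms <- names(chromClass)[chromClass == "sample"]
    spikeChroms <- names(chromClass)[chromClass == "spikein"]
    if (!length(spikeChroms))
        stop("architecture requires a spike-in chromosome")
    chromNames <- names(chromSizes)
    sizes <- unname(chromSizes)
    isSpike <- runif(n) < arch@spikeinFraction
    pw <- arch@promoterWeight; bw <- arch@bodyGradientWeight
    # chromCode indexes into chromNames; pos is the fragment midpoint
    chromCode <- integer(n); pos <- numeric(n)
    spikeLens <- chromSizes[spikeChroms]
    sIdx <- which(isSpike)
    if (length(sIdx)) {
        code <- match(spikeChroms, chromNames)[
            sample.int(length(spikeChroms), length(sIdx), replace = TRUE,
                       prob = spikeLens)]
        chromCode[sIdx] <- code
        pos[sIdx] <- runif(length(sIdx)) * sizes[code]
    }
    gIdx <- which(!isSpike)
    u <- runif(length(gIdx))
    geneCode <- match(as.character(seqnames(genes)), chromNames)
    tss0 <- unname(tssPositions(genes))
    gs0 <- start(genes) - 1; ge0 <- as.numeric(end(genes))
    minus <- as.character(strand(genes)) == "-"
    # background: uniform over the sample genome
    bgI <- gIdx[u >= pw + bw]
    if (length(bgI)) {
        sampLens <- chromSizes[sampleChroms]
        code <- match(sampleChroms, chromNames)[
            sample.int(length(sampleChroms), length(bgI), replace = TRUE,
                       prob = sampLens)]
        chromCode[bgI] <- code
        pos[bgI] <- runif(length(bgI)) * sizes[code]
    }
    # promoter component: Normal around a uniformly chosen TSS
    prI <- gIdx[u < pw]
    if (length(prI)) {
        gi <- sample.int(length(genes), length(prI), replace = TRUE)
        chromCode[prI] <- geneCode[gi]
        pos[prI] <- rnorm(length(prI), tss0[gi], arch@sigmaProm)
    }
    # body component: gradient rising 5'->3' over a chosen gene body
    boI <- gIdx[u >= pw & u < pw + bw]
    if (length(boI)) {
        gi <- sample.int(length(genes), length(boI), replace = TRUE)
        t <- .gradientQuantile(runif(length(boI)), arch@gradientSlope)
        len <- ge0[gi] - gs0[gi]
        p <- gs0[gi] + t * len
        m <- minus[gi]
        p[m] <- ge0[gi][m] - (t * len)[m]
        chromCode[boI] <- geneCode[gi]
        pos[boI] <- p
    }
    fragLen <- base::pmax(50, round(rnorm(n, arch@fragLenMean,
                                          arch@fragLenSd)))
    L <- sizes[chromCode]
    start0 <- round(pos - fragLen / 2)
    start0 <- base::pmin(base::pmax(start0, 0), L - 1)
    end0 <- base::pmin(start0 + fragLen, L)
    # group by chromosome (stable) so seqnames compress to a short Rle
    ord <- order(chromCode, method = "radix")
    chromCode <- chromCode[ord]; start0 <- start0[ord]; end0 <- end0[ord]
    gr <- GRanges(Rle(structure(chromCode, levels = chromNames,
                                class = "factor")),
                  IRanges(start0 + 1, end0))
    FragmentSet(gr, chromClass = chromClass, sampleId = sampleId,
                chromSizes = chromSizes)
}

#' Expected (noise-free) coverage of a signal architecture
#'
#' The deterministic bin-level expectation of
#' \code{\link{simulateFragments}}' midpoint distribution over the
#' sample chromosomes: per-bin probability mass of the
#' background/promoter/body mixture scaled to \code{totalMass}
#' fragment-bases. Useful as an analytic fixture (e.g. exact metagene
#' shapes) and as the distribution oracle for the sampler.
#'
#' @param genes named GRanges of gene models.
#' @param chromSizes named chromosome lengths.
#' @param chromClass named chromosome -> class map.
#' @param arch a \linkS4class{SignalArchitecture}.
#' @param binSize bin width in bases.
#' @param totalMass total signal mass distributed over the genome.
#' @return A \linkS4class{CoverageTrack} (units \code{"rrpm"}).
#' @export
expectedCoverage <- function(genes, chromSizes, chromClass, arch,
                             binSize = 50L, totalMass = 1e6) {
    binSize <- as.integer(binSize)
    sampleChroms <- names(chromClass)[chromClass == "sample"]
    pw <- arch@promoterWeight; bw <- arch@bodyGradientWeight
    bg <- 1 - pw - bw
    s <- arch@gradientSlope
    gradCdf <- function(t) {
        t <- pmin(pmax(t, 0), 1)
        (t + s * t^2 / 2) / (1 + s / 2)
    }
    totLen <- sum(chromSizes[sampleChroms])
    geneChrom <- as.character(seqnames(genes))
    tss0 <- tssPositions(genes)
    gs0 <- start(genes) - 1; ge0 <- as.numeric(end(genes))
    minus <- as.character(strand(genes)) == "-"
    nG <- length(genes)
    bins <- lapply(sampleChroms, function(chr) {
        len <- chromSizes[[chr]]
        nb <- as.integer(ceiling(len / binSize))
        edges <- pmin(seq.int(0L, nb) * binSize, len)
        mass <- bg * diff(edges) / totLen
        for (i in which(geneChrom == chr)) {
            if (pw > 0)
                mass <- mass + (pw / nG) *
                    diff(pnorm(edges, tss0[i], arch@sigmaProm))
            if (bw > 0) {
                tEdges <- if (minus[i]) (ge0[i] - edges) / (ge0[i] - gs0[i])
                          else (edges - gs0[i]) / (ge0[i] - gs0[i])
                cdf <- gradCdf(tEdges)
                mass <- mass + (bw / nG) *
                    (if (minus[i]) -diff(cdf) else diff(cdf))
            }
        }
        mass * totalMass
    })
    names(bins) <- sampleChroms
    coverageTrack(bins, binSize, chromSizes[sampleChroms],
                  units = "rrpm", scaleFactor = NA_real_)
}

# Architecture with the promoter component scaled by a KO effect and
# weights renormalized (fixed sequencing depth redistributes mass).
.koArchitecture <- function(arch, effect) {
    pw <- arch@promoterWeight * effect
    bw <- arch@bodyGradientWeight
    bg <- 1 - arch@promoterWeight - arch@bodyGradientWeight
    tot <- pw + bw + bg
    signalArchitecture(promoterWeight = pw / tot,
                       bodyGradientWeight = bw / tot,
                       spikeinFraction = arch@spikeinFraction,
                       sigmaProm = arch@sigmaProm,
                       gradientSlope = arch@gradientSlope,
                       fragLenMean = arch@fragLenMean,
                       fragLenSd = arch@fragLenSd)
}

#' Simulate a knockout screening panel
#'
#' Generates one screening round: KO targets are grouped into batches
#' of \code{batchSize}, each batch carries one wild-type sample and a
#' batch-level depth multiplier, and each KO sample is drawn with the
#' promoter component scaled by its effect (weights renormalized, as a
#' fixed sequencing depth implies). A truth table accompanies the
#' manifest.
#'
#' @param design a \linkS4class{PanelDesign}.
#' @param arch the wild-type \linkS4class{SignalArchitecture}.
#' @param genes,chromSizes,chromClass genome as from
#'   \code{\link{simulateGenome}}.
#' @param seed integer seed; per-sample seeds are derived from it.
#' @return list with \code{manifest} (sample_id, gene, batch, round,
#'   role), \code{fragments} (named list of FragmentSets) and
#'   \code{truth} (gene, effect).
#' @export
simulateKoPanel <- function(design, arch, genes, chromSizes,
                            chromClass, seed = NULL) {
    targets <- names(design@effects)
    nBatches <- ceiling(length(targets) / design@batchSize)
    batchOf <- rep(seq_len(nBatches), each = design@batchSize,
                   length.out = length(targets))
    mult <- rep(design@depthMultipliers,
                length.out = nBatches)
    rows <- list(); k <- 0L
    for (b in seq_len(nBatches)) {
        batchName <- sprintf("r%db%02d", design@round, b)
        k <- k + 1L
        rows[[k]] <- data.frame(
            sample_id = paste0(batchName, "_WT"), gene = "WT",
            batch = batchName, round = design@round, role = "WT",
            effect = 1, depth = round(design@baseDepth * mult[b]),
            stringsAsFactors = FALSE)
        for (g in targets[batchOf == b]) {
            k <- k + 1L
            rows[[k]] <- data.frame(
                sample_id = paste0(batchName, "_", g), gene = g,
                batch = batchName, round = design@round, role = "KO",
                effect = unname(design@effects[g]),
                depth = round(design@baseDepth * mult[b]),
                stringsAsFactors = FALSE)
        }
    }
    manifest <- do.call(rbind, rows)
    if (!is.null(seed)) set.seed(seed)
    sampleSeeds <- sample.int(.Machine$integer.max - 1L,
                              nrow(manifest))
    fragmentSets <- lapply(seq_len(nrow(manifest)), function(i) {
        row <- manifest[i, ]
        a <- if (row$role == "KO") .koArchitecture(arch, row$effect)
             else arch
        simulateFragments(genes, chromSizes, chromClass, a,
                          nFragments = row$depth,
                          seed = sampleSeeds[i],
                          sampleId = row$sample_id)
    })
    names(fragmentSets) <- manifest$sample_id
    list(manifest = manifest[, c("sample_id", "gene", "batch", "round",
                                 "role")],
         fragments = fragmentSets,
         truth = data.frame(gene = targets,
                            effect = unname(design@effects),
                            stringsAsFactors = FALSE))
}

#' End-to-end two-round screen on simulated data
#'
#' Simulates round 1 for the full panel, screens it, re-simulates
#' round 2 (an independent clone per gene, so fresh randomness) for the
#' genes whose round-1 call was not "unchanged", screens again, and
#' confirms hits. Mirrors the two-round design in which only targets
#' near or beyond the criterion advance.
#'
#' @param design a \linkS4class{PanelDesign} for round 1.
#' @param arch wild-type \linkS4class{SignalArchitecture}.
#' @param genes,chromSizes,chromClass genome.
#' @param seed integer seed; round 2 uses a derived seed.
#' @param threshold screening criterion (default 0.15).
#' @param binSize,constant coverage parameters.
#' @return list with \code{calls1}, \code{calls2}, \code{hits},
#'   \code{truth}.
#' @export
runScreenSimulation <- function(design, arch, genes, chromSizes,
                                chromClass, seed = 1L,
                                threshold = 0.15, binSize = 50L,
                                constant = 1e6) {
    panel1 <- simulateKoPanel(design, arch, genes, chromSizes,
                              chromClass, seed = seed)
    round1 <- screenRound(panel1$fragments, panel1$manifest, genes,
                          binSize = binSize, constant = constant,
                          threshold = threshold)
    candidates <- round1$calls$gene[round1$calls$call != "unchanged"]
    if (length(candidates)) {
        design2 <- panelDesign(design@effects[candidates],
                               baseDepth = design@baseDepth,
                               batchSize = design@batchSize,
                               depthMultipliers = design@depthMultipliers,
                               round = 2L)
        panel2 <- simulateKoPanel(design2, arch, genes, chromSizes,
                                  chromClass, seed = seed + 1000003L)
        round2 <- screenRound(panel2$fragments, panel2$manifest, genes,
                              binSize = binSize, constant = constant,
                              threshold = threshold)
        calls2 <- round2$calls
    } else {
        calls2 <- data.frame(gene = character(), batch = character(),
                             round = integer(), wtIndex = numeric(),
                             koIndex = numeric(), ratio = numeric(),
                             call = character())
    }
    hits <- confirmHits(round1$calls[, c("gene", "call")],
                        calls2[, c("gene", "call")])
    list(calls1 = round1$calls, calls2 = calls2, hits = hits,
         truth = data.frame(gene = names(design@effects),
                            effect = unname(design@effects),
                            stringsAsFactors = FALSE))
}

#' Simulate replicate expression counts linked to promoter effects
#'
#' Negative-binomial counts for two conditions with per-gene baseline
#' means drawn log-normally around \code{baseMean}; genes with an
#' injected log2 fold change realize it in expectation in the KO
#' condition.
#'
#' @param genes named GRanges (lengths taken from widths) or a
#'   character vector of gene ids (then \code{lengths} must be given).
#' @param nReps replicates per condition (>= 2).
#' @param baseMean median baseline expected count.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param log2fc named numeric of injected fold changes (default all
#'   0); names must be gene ids.
#' @param seed optional integer seed.
#' @param lengths named gene lengths when \code{genes} is a character
#'   vector.
#' @return list with count matrices \code{wt} and \code{ko}, gene
#'   \code{lengths}, and the injected \code{log2fc}.
#' @export
simulateExpression <- function(genes, nReps = 3L, baseMean = 500,
                               dispersion = 0.05, log2fc = NULL,
                               seed = NULL, lengths = NULL) {
    if (is(genes, "GRanges")) {
        ids <- names(genes)
        lengths <- setNames(as.numeric(width(genes)), ids)
    } else {
        ids <- as.character(genes)
        if (is.null(lengths))
            stop("'lengths' required when genes are given as ids")
    }
    if (nReps < 2) stop("need >= 2 replicates per condition")
    if (!is.null(seed)) set.seed(seed)
    G <- length(ids)
    lfc <- setNames(numeric(G), ids)
    if (!is.null(log2fc)) lfc[names(log2fc)] <- log2fc
    mu <- exp(rnorm(G, log(baseMean), 0.6))
    size <- 1 / dispersion
    draw <- function(m) matrix(rnbinom(G * nReps, mu = rep(m, nReps),
                                       size = size),
                               nrow = G,
                               dimnames = list(ids,
                                               paste0("rep",
                                                      seq_len(nReps))))
    wt <- draw(mu)
    ko <- draw(mu * 2^lfc)
    list(wt = wt, ko = ko, lengths = lengths, log2fc = lfc)
}
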