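# Independent brute-force oracles and tiny fixture builders used across
# the suite. Everything here recomputes quantities per base with naive
# loops, deliberately sharing no code with the package internals.

# Per-base coverage depth (fragment count covering each base) from
# 0-based half-open fragment coordinates.
perBaseCoverage <- function(start0, end0, chromLen) {
    d <- numeric(chromLen)
    for (i in seq_along(start0)) {
        s <- max(start0[i], 0) + 1
        e <- min(end0[i], chromLen)
        if (e >= s) d[s:e] <- d[s:e] + 1
    }
    d
}

# Mean of a per-base density over a 0-based half-open region; bases
# beyond the vector count as zero signal.
perBaseRegionMean <- function(dens, s0, e0) {
    idx <- seq.int(s0 + 1, e0)
    vals <- numeric(length(idx))
    inb <- idx >= 1 & idx <= length(dens)
    vals[inb] <- dens[idx[inb]]
    sum(vals) / (e0 - s0)
}

# Expand a binned track into its implied per-base density vector.
trackPerBaseDensity <- function(track, chr) {
    bins <- binValues(track)[[chr]]
    bs <- binSize(track)
    len <- track@chromLengths[[chr]]
    widths <- rep(bs, length(bins))
    widths[length(bins)] <- len - (length(bins) - 1) * bs
    rep(bins / widths, times = widths)
}

# Build a CoverageTrack directly from a per-base density vector.
densityTrack <- function(dens, binSize = 1L, chrom = "chr1") {
    len <- length(dens)
    nb <- ceiling(len / binSize)
    sums <- vapply(seq_len(nb), function(b) {
        lo <- (b - 1) * binSize + 1
        hi <- min(b * binSize, len)
        sum(dens[lo:hi])
    }, numeric(1))
    coverageTrack(setNames(list(sums), chrom), binSize,
                  setNames(len, chrom))
}

# Two-sided Fisher's exact p-value by exhaustive enumeration of all
# tables with the observed margins (hypergeometric probabilities;
# tables as or less probable than the observed one, with the classical
# 1e-7 relative tolerance).
enumFisherP <- function(n11, n10, n01, n00) {
    m <- n11 + n10          # row 1 total
    k <- n11 + n01          # col 1 total
    n <- n11 + n10 + n01 + n00
    xs <- max(0, k + m - n):min(k, m)
    probs <- vapply(xs, function(x)
        choose(m, x) * choose(n - m, k - x) / choose(n, k), numeric(1))
    pObs <- probs[match(n11, xs)]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Small deterministic gene fixture on one chromosome (+ spike-in).
tinyGenome <- function() {
    chromSizes <- c(chr1 = 50000, spike = 5000)
    genes <- GenomicRanges::GRanges(
        factor(c("chr1", "chr1"), levels = names(chromSizes)),
        IRanges::IRanges(start = c(10001, 30001), end = c(15000, 36000)),
        strand = c("+", "-"))
    names(genes) <- c("gA", "gB")
    GenomeInfoDb::seqlengths(genes) <- chromSizes
    list(genes = genes, chromSizes = chromSizes,
         chromClass = c(chr1 = "sample", spike = "spikein"))
}

# FragmentSet from 0-based half-open coordinate vectors.
makeFragments <- function(chrom, start0, end0, chromSizes, chromClass,
                          sampleId = "fix") {
    gr <- GenomicRanges::GRanges(
        factor(chrom, levels = names(chromSizes)),
        IRanges::IRanges(start0 + 1, end0))
    FragmentSet(gr, chromClass = chromClass, sampleId = sampleId,
                chromSizes = chromSizes)
}
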