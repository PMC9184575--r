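#' Count fragments by reference class
#'
#' @param fs a \linkS4class{FragmentSet}.
#' @return named numeric vector with elements \code{sample} and
#'   \code{spikein}; the two sum to \code{length(fs)}.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr1", "ecoli"),
#'     IRanges::IRanges(c(1, 1), c(100, 80)))
#' fs <- FragmentSet(gr, c(chr1 = "sample", ecoli = "spikein"),
#'     chromSizes = c(chr1 = 1000, ecoli = 500))
#' countByRefClass(fs)
#' @export
countByRefClass <- function(fs) {
    if (length(fs) == 0L) stop("empty FragmentSet")
    nSpike <- sum(refClass(fs) == "spikein")
    c(sample = length(fs) - nSpike, spikein = nSpike)
}

#' Spike-in scale factor
#'
#' The per-sample normalization factor \code{constant / spikein_reads}
#' that puts coverage on the reference-adjusted reads-per-million scale:
#' more spike-in reads mean a deeper library, so its signal is scaled
#' down proportionally.
#'
#' @param spikeinReads fragments mapped to the exogenous reference.
#' @param constant numerator constant (default 1e6, i.e. "per million").
#' @return A \linkS4class{ScaleFactor}.
#' @examples
#' sfValue(computeScaleFactor(5e5))  # 2
#' @export
computeScaleFactor <- function(spikeinReads, constant = 1e6) {
    if (length(spikeinReads) != 1L || is.na(spikeinReads) ||
        spikeinReads <= 0)
        stop("spike-in read count must be > 0; for libraries without a ",
             "spike-in reference use the no-spike-in mode ",
             "(scale by constant / sample_reads)")
    new("ScaleFactor", constant = constant,
        spikeinReads = as.numeric(spikeinReads),
        value = constant / spikeinReads)
}

#' Binned coverage from fragments
#'
#' Converts the sample-class fragments of a set into per-chromosome bin
#' vectors where each fragment contributes its overlap length (in bases)
#' to each bin, so the genome-wide bin total equals the summed (clipped)
#' fragment lengths. Spike-in chromosomes are excluded from the track;
#' they only contribute to the scale-factor denominator.
#'
#' @param fs a \linkS4class{FragmentSet}.
#' @param binSize bin width in bases (default 50).
#' @return A \linkS4class{CoverageTrack} with units
#'   \code{"fragment_bases"}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' fs <- FragmentSet(gr, c(chr1 = "sample"), chromSizes = c(chr1 = 100))
#' binValues(fragmentsToCoverage(fs, binSize = 50))$chr1  # 50 50
#' @export
fragmentsToCoverage <- function(fs, binSize = 50L) {
    binSize <- as.integer(binSize)
    if (binSize < 1L) stop("binSize must be >= 1")
    gr <- fragments(fs)
    chroms <- names(fs@chromClass)[fs@chromClass == "sample"]
    if (!length(chroms)) stop("no sample-class chromosomes in FragmentSet")
    sl <- seqlengths(gr)[chroms]
    gr <- gr[gr$refClass == "sample"]
    bins <- lapply(chroms, function(chr) {
        len <- as.integer(sl[[chr]])
        nb <- as.integer(ceiling(len / binSize))
        ir <- ranges(gr[seqnames(gr) == chr])
        cov <- coverage(ir, width = len)
        widths <- rep(binSize, nb)
        widths[nb] <- len - (nb - 1L) * binSize
        as.numeric(viewSums(Views(cov, successiveIRanges(widths))))
    })
    names(bins) <- chroms
    new("CoverageTrack", bins = bins, binSize = binSize,
        chromLengths = setNames(as.numeric(sl), chroms),
        units = "fragment_bases", scaleFactor = NA_real_)
}

#' Apply a spike-in scale factor to a coverage track
#'
#' Multiplies every bin by the factor, yielding normalized
#' reference-adjusted coverage ("Norm. RRPM").
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param sf a \linkS4class{ScaleFactor} (or a single positive number).
#' @return A normalized \linkS4class{CoverageTrack} (units
#'   \code{"rrpm"}).
#' @export
normalizeTrack <- function(track, sf) {
    value <- if (is(sf, "ScaleFactor")) sfValue(sf) else as.numeric(sf)
    if (!is.finite(value) || value <= 0)
        stop("scale factor must be finite and > 0")
    new("CoverageTrack", bins = lapply(track@bins, `*`, value),
        binSize = track@binSize, chromLengths = track@chromLengths,
        units = "rrpm", scaleFactor = value)
}

# Per-chromosome bin widths (last bin may be short).
.binWidths <- function(track, chr) {
    len <- track@chromLengths[[chr]]
    nb <- length(track@bins[[chr]])
    widths <- rep(track@binSize, nb)
    widths[nb] <- len - (nb - 1L) * track@binSize
    widths
}

# Evaluator of the cumulative signal S(x) = integral over [0, x) of the
# per-base signal density implied by the binned track (piecewise constant
# within bins). x outside [0, chrom length] is clamped: positions beyond
# the chromosome carry zero signal.
.cumSignalEvaluator <- function(track, chr) {
    vals <- track@bins[[chr]]
    widths <- .binWidths(track, chr)
    len <- track@chromLengths[[chr]]
    bs <- track@binSize
    nb <- length(vals)
    cum <- c(0, cumsum(vals))
    dens <- vals / widths
    function(x) {
        x <- base::pmin(base::pmax(x, 0), len)
        fb <- base::pmin(floor(x / bs), nb - 1L)
        cum[fb + 1L] + (x - fb * bs) * dens[fb + 1L]
    }
}

#' Mean signal density over regions
#'
#' Mean per-base signal (bin value / bin width, i.e. coverage depth in
#' the track's units) over each region, computed exactly from the binned
#' track with fractional-bin overlap weighting. Parts of a region beyond
#' the chromosome end contribute zero signal but still count in the
#' denominator.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param regions GRanges on the track's chromosomes.
#' @return numeric vector, one mean per region (named like
#'   \code{regions}).
#' @export
regionMeanSignal <- function(track, regions) {
    chroms <- as.character(seqnames(regions))
    unknown <- setdiff(chroms, names(track@bins))
    if (length(unknown))
        stop("region(s) on chromosome(s) absent from track: ",
             paste(unique(unknown), collapse = ", "))
    out <- numeric(length(regions))
    for (chr in unique(chroms)) {
        idx <- which(chroms == chr)
        S <- .cumSignalEvaluator(track, chr)
        s0 <- start(regions)[idx] - 1
        e0 <- end(regions)[idx]
        out[idx] <- (S(e0) - S(s0)) / (e0 - s0)
    }
    names(out) <- names(regions)
    out
}

#' Write / read a coverage track as bedGraph
#'
#' Exports per-base signal density (bin value / bin width, the
#' genome-browser convention) as bedGraph intervals via rtracklayer,
#' merging runs of equal-valued adjacent bins and omitting zero runs.
#' Reading distributes the interval values back into bins; the round
#' trip is exact when intervals align to bin boundaries (as exported
#' ones do).
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path bedGraph file.
#' @return \code{writeBedGraph}: \code{path}, invisibly;
#'   \code{readBedGraph}: a \linkS4class{CoverageTrack}.
#' @export
writeBedGraph <- function(track, path) {
    grl <- lapply(names(track@bins), function(chr) {
        widths <- .binWidths(track, chr)
        dens <- track@bins[[chr]] / widths
        ends <- cumsum(widths)
        r <- rle(dens)
        i2 <- cumsum(r$lengths)
        i1 <- c(1L, head(i2, -1L) + 1L)
        keep <- r$values != 0
        GRanges(chr, IRanges(ends[i1[keep]] - widths[i1[keep]] + 1L,
                             ends[i2[keep]]),
                score = r$values[keep])
    })
    gr <- suppressWarnings(do.call(c, grl))
    seqlevels(gr) <- names(track@chromLengths)
    seqlengths(gr) <- track@chromLengths
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname writeBedGraph
#' @param chromSizes named chromosome lengths for the reconstructed
#'   track.
#' @param binSize bin width of the reconstructed track.
#' @param units units to record on the track.
#' @export
readBedGraph <- function(path, chromSizes, binSize = 50L,
                         units = "rrpm") {
    binSize <- as.integer(binSize)
    gr <- rtracklayer::import(path, format = "bedGraph")
    chrom <- as.character(seqnames(gr))
    unknown <- setdiff(chrom, names(chromSizes))
    if (length(unknown))
        stop("bedGraph chromosome(s) absent from chromSizes: ",
             paste(unique(unknown), collapse = ", "))
    s0 <- start(gr) - 1; e0 <- end(gr); val <- gr$score
    bins <- lapply(names(chromSizes), function(chr) {
        len <- chromSizes[[chr]]
        nb <- as.integer(ceiling(len / binSize))
        v <- numeric(nb)
        for (i in which(chrom == chr)) {
            if (e0[i] <= s0[i] || val[i] == 0) next
            b1 <- floor(s0[i] / binSize)
            b2 <- floor((e0[i] - 1) / binSize)
            for (b in b1:b2) {
                lo <- max(s0[i], b * binSize)
                hi <- min(e0[i], (b + 1) * binSize, len)
                if (hi > lo) v[b + 1L] <- v[b + 1L] + val[i] * (hi - lo)
            }
        }
        v
    })
    names(bins) <- names(chromSizes)
    new("CoverageTrack", bins = bins, binSize = binSize,
        chromLengths = setNames(as.numeric(chromSizes),
                                names(chromSizes)),
        units = units, scaleFactor = NA_real_)
}

#' One-call coverage + normalization from a FragmentSet
#'
#' Convenience wrapper: counts reference classes, derives the scale
#' factor (spike-in by default, or library-size scaling in no-spike-in
#' mode to avoid over-normalization when spike-in content is unreliable),
#' bins the sample fragments, and normalizes.
#'
#' @param fs a \linkS4class{FragmentSet}.
#' @param binSize bin width in bases.
#' @param constant scale-factor numerator.
#' @param spikein use the spike-in denominator (TRUE) or the sample read
#'   count (no-spike-in mode).
#' @return A normalized \linkS4class{CoverageTrack}.
#' @export
normalizedCoverage <- function(fs, binSize = 50L, constant = 1e6,
                               spikein = TRUE) {
    counts <- countByRefClass(fs)
    denom <- if (spikein) counts[["spikein"]] else counts[["sample"]]
    sf <- computeScaleFactor(denom, constant)
    normalizeTrack(fragmentsToCoverage(fs, binSize), sf)
}

#' Build a CoverageTrack directly from bin values
#'
#' Mainly for constructing deterministic, noise-free fixtures (e.g. the
#' expected coverage of a signal architecture).
#'
#' @param bins named list of per-chromosome numeric vectors (bin sums,
#'   fragment-bases per bin in the track's units).
#' @param binSize bin width in bases.
#' @param chromLengths named chromosome lengths.
#' @param units track units.
#' @param scaleFactor factor recorded on the track.
#' @return A \linkS4class{CoverageTrack}.
#' @export
coverageTrack <- function(bins, binSize, chromLengths,
                          units = "rrpm", scaleFactor = NA_real_) {
    new("CoverageTrack", bins = bins, binSize = as.integer(binSize),
        chromLengths = setNames(as.numeric(chromLengths),
                                names(chromLengths)),
        units = units, scaleFactor = scaleFactor)
}
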