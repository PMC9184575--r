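#' Simple quantile-threshold peak caller
#'
#' A transparent stand-in for heavyweight peak callers: bins whose
#' signal density is strictly above the genome-wide
#' \code{thresholdQuantile} quantile are merged when separated by at
#' most \code{mergeGap} bases, and merged runs shorter than
#' \code{minWidth} are dropped. Every downstream operation also accepts
#' externally produced peaks (any GRanges), so real-data users can
#' substitute a dedicated caller.
#'
#' @param track a normalized \linkS4class{CoverageTrack}.
#' @param thresholdQuantile genome-wide density quantile (default 0.99).
#' @param minWidth minimum peak width in bases (default 200).
#' @param mergeGap maximum gap merged between above-threshold runs
#'   (default 150).
#' @return GRanges of peaks with a \code{score} column (mean normalized
#'   signal) and the caller parameters in \code{metadata()}; empty for
#'   an all-zero track.
#' @export
callPeaksSimple <- function(track, thresholdQuantile = 0.99,
                            minWidth = 200L, mergeGap = 150L) {
    dens <- unlist(lapply(names(track@bins), function(chr)
        track@bins[[chr]] / .binWidths(track, chr)), use.names = FALSE)
    if (!length(dens)) stop("empty track")
    thr <- quantile(dens, thresholdQuantile, names = FALSE)
    peaks <- lapply(names(track@bins), function(chr) {
        widths <- .binWidths(track, chr)
        d <- track@bins[[chr]] / widths
        sel <- d > thr
        if (!any(sel)) return(GRanges())
        ends <- cumsum(widths)
        starts0 <- ends - widths
        ir <- reduce(IRanges(starts0[sel] + 1L, ends[sel]),
                     min.gapwidth = mergeGap + 1L)
        ir <- ir[width(ir) >= minWidth]
        if (!length(ir)) return(GRanges())
        GRanges(chr, ir)
    })
    out <- suppressWarnings(do.call(c, peaks))
    seqlevels(out) <- names(track@chromLengths)
    seqlengths(out) <- track@chromLengths
    if (length(out)) out$score <- regionMeanSignal(track, out)
    else out$score <- numeric(0)
    metadata(out) <- list(thresholdQuantile = thresholdQuantile,
                          minWidth = minWidth, mergeGap = mergeGap,
                          threshold = thr)
    out
}

#' Write peaks as BED6 (+ exact score TSV column)
#'
#' Column 5 carries the score rescaled to 0-1000 (BED convention);
#' column 7 the exact mean normalized signal.
#'
#' @param peaks GRanges with a \code{score} column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(peaks, path) {
    sc <- peaks$score %||% rep(0, length(peaks))
    bedScore <- if (length(sc) && max(sc) > 0)
        as.integer(round(1000 * sc / max(sc))) else integer(length(sc))
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     name = paste0("peak", seq_along(peaks)),
                     score = bedScore, strand = ".", exact_score = sc)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Two-sided Fisher's exact test of a 2x2 table
#'
#' @param n11,n10,n01,n00 cell counts (in A and B, A only, B only,
#'   neither).
#' @return list with \code{pValue} and \code{oddsRatio}.
#' @export
fisherExactTable <- function(n11, n10, n01, n00) {
    tab <- matrix(c(n11, n10, n01, n00), nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    list(pValue = ft$p.value, oddsRatio = unname(ft$estimate))
}

#' Peak-set overlap with a Fisher's exact test
#'
#' Classifies every universe region (e.g. all promoters, or genome
#' bins) by whether it intersects an A peak and whether it intersects a
#' B peak, and tests the 2x2 table with a two-sided Fisher's exact
#' test. The universe must be stated explicitly; it determines the
#' null.
#'
#' @param a,b GRanges peak sets.
#' @param universe non-empty GRanges of candidate regions covering the
#'   peaks.
#' @return An \linkS4class{OverlapResult}.
#' @export
overlapTest <- function(a, b, universe) {
    if (!length(universe)) stop("empty universe")
    inA <- overlapsAny(universe, a)
    inB <- overlapsAny(universe, b)
    tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                    sum(!inA & inB), sum(!inA & !inB)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(A = c("in", "out"),
                                  B = c("in", "out")))
    ft <- fisherExactTable(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    new("OverlapResult", nA = length(a), nB = length(b),
        nOverlap = sum(overlapsAny(a, b)),
        universeSize = length(universe), table = tab,
        oddsRatio = ft$oddsRatio, pValue = ft$pValue)
}

#' Per-promoter signal matrix across tracks
#'
#' Mean normalized signal of each track over each promoter, optionally
#' restricted to promoters overlapping a peak set (e.g. promoters that
#' overlap the H3K36me3 peaks of the reference condition).
#'
#' @param tracks named list of \linkS4class{CoverageTrack}s.
#' @param promoters named GRanges of promoter windows.
#' @param restrictTo optional GRanges; promoters not overlapping it are
#'   dropped (an empty result is an error).
#' @return numeric matrix, rows = promoters, columns = tracks.
#' @export
promoterSignalTable <- function(tracks, promoters, restrictTo = NULL) {
    if (is.null(names(tracks)))
        names(tracks) <- paste0("track", seq_along(tracks))
    if (!is.null(restrictTo)) {
        promoters <- promoters[overlapsAny(promoters, restrictTo)]
        if (!length(promoters))
            stop("restriction to the peak set leaves no promoters")
    }
    mat <- vapply(tracks, regionMeanSignal, numeric(length(promoters)),
                  regions = promoters)
    mat <- matrix(mat, nrow = length(promoters),
                  dimnames = list(names(promoters), names(tracks)))
    mat
}

#' Pearson correlation with a least-squares line
#'
#' Pearson product-moment R with its two-sided p-value from the
#' t-distribution transform, plus the ordinary least-squares slope and
#' intercept of y on x.
#'
#' @param x,y finite numeric vectors of equal length >= 3 with nonzero
#'   variance. When both are named, names must match (aligned rows).
#' @param log10 correlate log10(value + eps) instead of raw values.
#' @param eps offset used by \code{log10}.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' correlateSignals(1:3, c(2, 4, 6))   # R = 1, slope = 2
#' @export
correlateSignals <- function(x, y, log10 = FALSE, eps = 1e-3) {
    if (!is.null(names(x)) && !is.null(names(y))) {
        if (!identical(names(x), names(y)))
            stop("x and y rows are misaligned (names differ)")
    }
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 points")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("x and y must be finite")
    if (log10) { x <- log10(x + eps); y <- log10(y + eps) }
    if (sd(x) == 0 || sd(y) == 0)
        stop("zero variance in x or y; correlation undefined")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    slope <- cov(x, y) / var(x)
    new("CorrelationResult", r = unname(ct$estimate),
        pValue = ct$p.value, n = length(x), slope = slope,
        intercept = mean(y) - slope * mean(x))
}

#' Correlate per-promoter signal changes with writer occupancy
#'
#' The rescue-style analysis: the difference in normalized mark signal
#' between two conditions at each promoter (condition A - condition B)
#' against the writer-protein occupancy at the same promoters. The
#' regression slope measures how much mark is restored per unit of
#' writer bound.
#'
#' @param delta named numeric per-promoter signal differences.
#' @param occupancy named numeric per-promoter writer signal, aligned
#'   with \code{delta} (mismatched names are an error).
#' @param ... passed to \code{\link{correlateSignals}}.
#' @return A \linkS4class{CorrelationResult} of \code{delta} on
#'   \code{occupancy}.
#' @export
deltaVsOccupancy <- function(delta, occupancy, ...) {
    if (!is.null(names(delta)) && !is.null(names(occupancy)) &&
        !identical(names(delta), names(occupancy)))
        stop("delta and occupancy promoter rows are misaligned")
    correlateSignals(occupancy, delta, ...)
}

#' Paired t-test between two aligned signal vectors
#'
#' Companion statistic for correlation panels: a two-sided paired
#' t-test between the two per-region signal vectors.
#'
#' @param x,y aligned numeric vectors.
#' @return two-sided p-value.
#' @export
pairedSignalTest <- function(x, y) {
    t.test(x, y, paired = TRUE, alternative = "two.sided")$p.value
}
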