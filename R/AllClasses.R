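#' FragmentSet: sequenced fragment intervals with reference-class labels
#'
#' Holds the fragment intervals of one sequenced sample as a
#' \link[GenomicRanges]{GRanges} (1-based closed, converted from BED
#' 0-based half-open at the I/O boundary) together with the chromosome ->
#' reference-class map that labels every fragment as \code{"sample"}
#' (the profiled genome) or \code{"spikein"} (the exogenous reference
#' carried along for normalization). The class is assigned from the
#' chromosome a fragment names, never inferred from coordinates.
#'
#' @slot fragments GRanges with complete seqlengths and a \code{refClass}
#'   metadata column.
#' @slot chromClass named character vector mapping every chromosome to
#'   \code{"sample"} or \code{"spikein"}.
#' @slot sampleId single character identifier.
#'
#' @aliases FragmentSet
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(
        fragments = "GRanges",
        chromClass = "character",
        sampleId = "character"
    )
)

setValidity("FragmentSet", function(object) {
    gr <- object@fragments
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
        return("all chromosomes must have known lengths (seqlengths)")
    if (!all(seqlevels(gr) %in% names(object@chromClass)))
        return("every chromosome must appear in chromClass")
    if (!all(object@chromClass %in% c("sample", "spikein")))
        return("chromClass values must be 'sample' or 'spikein'")
    rc <- gr$refClass
    if (is.null(rc))
        return("fragments must carry a refClass metadata column")
    lev <- if (is.factor(rc)) levels(rc)
           else if (is(rc, "Rle")) as.character(runValue(rc))
           else unique(rc)
    if (!all(lev %in% c("sample", "spikein")))
        return("refClass values must be 'sample' or 'spikein'")
    if (length(gr)) {
        if (any(start(gr) < 1L))
            return("fragment start below chromosome start")
        if (any(end(gr) > sl[seqlevels(gr)][as.integer(seqnames(gr))]))
            return("fragment end exceeds chromosome length")
    }
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    TRUE
})

#' Construct a FragmentSet
#'
#' @param fragments GRanges of fragment intervals; seqlengths must be set
#'   (use \code{chromSizes} to supply them).
#' @param chromClass named character vector chromosome -> reference class
#'   (\code{"sample"} or \code{"spikein"}); chromosomes absent from the
#'   map are an error.
#' @param sampleId sample identifier stored with the object.
#' @param chromSizes optional named vector of chromosome lengths used to
#'   (re)set seqlengths on \code{fragments}.
#' @return A \linkS4class{FragmentSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' fs <- FragmentSet(gr, c(chr1 = "sample"), chromSizes = c(chr1 = 1000))
#' @export
FragmentSet <- function(fragments, chromClass, sampleId = "sample",
                        chromSizes = NULL) {
    if (!is(fragments, "GRanges"))
        stop("'fragments' must be a GRanges")
    if (!is.null(chromSizes)) {
        seqlevels(fragments) <- names(chromSizes)
        seqlengths(fragments) <- chromSizes
    }
    missing <- setdiff(seqlevels(fragments), names(chromClass))
    if (length(missing))
        stop("chromosome(s) not in chromClass map: ",
             paste(missing, collapse = ", "))
    clsCode <- match(chromClass[seqlevels(fragments)],
                     c("sample", "spikein"))
    sn <- seqnames(fragments)
    fragments$refClass <-
        Rle(structure(clsCode[as.integer(runValue(sn))],
                      levels = c("sample", "spikein"),
                      class = "factor"),
            runLength(sn))
    new("FragmentSet", fragments = fragments,
        chromClass = chromClass[seqlevels(fragments)],
        sampleId = as.character(sampleId))
}

#' CoverageTrack: binned genome coverage, raw or spike-in normalized
#'
#' Per-chromosome vectors of binned signal over the sample-class
#' chromosomes. Raw units are fragment-bases per bin (each fragment
#' contributes its overlap length with each bin); after
#' \code{\link{normalizeTrack}} every bin has been multiplied by the
#' spike-in scale factor and the units become "Norm. RRPM"
#' (normalized reference-adjusted reads per million).
#'
#' @slot bins named list of numeric per-chromosome bin vectors.
#' @slot binSize bin width in bases.
#' @slot chromLengths named numeric chromosome lengths.
#' @slot units \code{"fragment_bases"} or \code{"rrpm"}.
#' @slot scaleFactor applied scale factor (NA when raw).
#'
#' @aliases CoverageTrack
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    representation(
        bins = "list",
        binSize = "integer",
        chromLengths = "numeric",
        units = "character",
        scaleFactor = "numeric"
    )
)

setValidity("CoverageTrack", function(object) {
    if (object@binSize < 1L) return("binSize must be >= 1")
    if (!identical(names(object@bins), names(object@chromLengths)))
        return("bins and chromLengths must name the same chromosomes")
    nb <- ceiling(object@chromLengths / object@binSize)
    if (!all(lengths(object@bins) == nb))
        return("bin vector length must be ceiling(chrom_length / binSize)")
    if (any(vapply(object@bins, function(v) any(v < 0), logical(1))))
        return("bin values must be non-negative")
    if (!object@units %in% c("fragment_bases", "rrpm"))
        return("units must be 'fragment_bases' or 'rrpm'")
    TRUE
})

#' ScaleFactor: exogenous spike-in normalization factor
#'
#' The per-sample scale factor \code{constant / spikein_reads} used to put
#' samples on a common reference-adjusted scale.
#'
#' @slot constant numerator constant (default 1e6, "reads per million").
#' @slot spikeinReads number of fragments mapped to the spike-in genome.
#' @slot value the ratio.
#' @aliases ScaleFactor
#' @exportClass ScaleFactor
setClass("ScaleFactor",
    representation(constant = "numeric", spikeinReads = "numeric",
                   value = "numeric"))

setValidity("ScaleFactor", function(object) {
    if (!is.finite(object@value) || object@value <= 0)
        return("scale factor value must be finite and > 0")
    TRUE
})

#' MetageneMatrix: genes x scaled-position signal matrix
#'
#' A scale-regions matrix: for every gene, fixed-width flank bins upstream
#' of the TSS, a fixed number of equal subdivisions of the gene body
#' (TSS to TES), and flank bins downstream of the TES, all oriented
#' 5' to 3' (rows for minus-strand genes are reversed genomic order).
#' Cells hold mean normalized signal.
#'
#' @slot values numeric matrix, rownames = gene ids.
#' @slot flankBp flank extent in bases.
#' @slot binSize flank bin width in bases (the coverage bin size).
#' @slot bodyBins number of body subdivisions.
#' @slot excluded gene ids excluded (e.g. below minimum length).
#' @aliases MetageneMatrix
#' @exportClass MetageneMatrix
setClass("MetageneMatrix",
    representation(values = "matrix", flankBp = "integer",
                   binSize = "integer", bodyBins = "integer",
                   excluded = "character"))

setValidity("MetageneMatrix", function(object) {
    expected <- 2L * (object@flankBp %/% object@binSize) + object@bodyBins
    if (ncol(object@values) != expected)
        return("column count must be 2*(flankBp/binSize) + bodyBins")
    if (is.null(rownames(object@values)))
        return("rows must be named by gene id")
    TRUE
})

#' IndexResult: the promoter/gene-body H3K36me3 index of one sample
#'
#' Mean normalized signal over promoter regions (TSS +/- halfwidth) and
#' over gene-body regions (offset downstream of TSS to TES), and their
#' ratio -- the screening indicator.
#'
#' @slot sampleId sample identifier.
#' @slot promoterSignal mean normalized signal at promoters.
#' @slot genebodySignal mean normalized signal over gene bodies.
#' @slot index promoterSignal / genebodySignal.
#' @slot nGenes number of eligible genes (non-empty body).
#' @slot batch experiment batch label (NA if unset).
#' @aliases IndexResult
#' @exportClass IndexResult
setClass("IndexResult",
    representation(sampleId = "character", promoterSignal = "numeric",
                   genebodySignal = "numeric", index = "numeric",
                   nGenes = "integer", batch = "character"))

#' OverlapResult: Fisher's exact test of peak-set overlap
#'
#' @slot nA,nB peak counts in the two sets.
#' @slot nOverlap number of A peaks intersecting at least one B peak.
#' @slot universeSize number of candidate regions tested.
#' @slot table the 2x2 contingency table over the universe.
#' @slot oddsRatio conditional MLE odds ratio.
#' @slot pValue two-sided Fisher's exact p-value.
#' @aliases OverlapResult
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(nA = "integer", nB = "integer", nOverlap = "integer",
                   universeSize = "integer", table = "matrix",
                   oddsRatio = "numeric", pValue = "numeric"))

#' CorrelationResult: Pearson correlation with a linear fit
#'
#' @slot r Pearson product-moment correlation coefficient.
#' @slot pValue two-sided p-value from the t-distribution transform.
#' @slot n number of points.
#' @slot slope,intercept ordinary least-squares fit of y on x.
#' @aliases CorrelationResult
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(r = "numeric", pValue = "numeric", n = "integer",
                   slope = "numeric", intercept = "numeric"))

#' SignalArchitecture: generative model of CUT&Tag-like fragment placement
#'
#' Mixture components emulating the observed phenomenology: a uniform
#' background, a promoter-centered Gaussian component (Normal(TSS,
#' sigmaProm)), a gene-body component whose density rises linearly from
#' TSS to TES (f(t) proportional to 1 + gradientSlope * t, t in [0,1]
#' along 5'->3'), and spike-in fragments placed uniformly on the
#' spike-in reference. Weights are fractions of non-spike-in fragments;
#' the background weight is the remainder.
#'
#' @slot promoterWeight fraction drawn from the promoter component.
#' @slot bodyGradientWeight fraction drawn from the gene-body gradient.
#' @slot spikeinFraction fraction of all fragments on the spike-in genome.
#' @slot sigmaProm promoter component standard deviation (bases).
#' @slot gradientSlope slope of the body gradient density.
#' @slot fragLenMean,fragLenSd fragment length Normal parameters (bases);
#'   lengths are clipped at 50 bp.
#' @aliases SignalArchitecture
#' @exportClass SignalArchitecture
setClass("SignalArchitecture",
    representation(promoterWeight = "numeric",
                   bodyGradientWeight = "numeric",
                   spikeinFraction = "numeric",
                   sigmaProm = "numeric",
                   gradientSlope = "numeric",
                   fragLenMean = "numeric",
                   fragLenSd = "numeric"))

setValidity("SignalArchitecture", function(object) {
    if (object@promoterWeight < 0 || object@bodyGradientWeight < 0)
        return("component weights must be >= 0")
    if (object@promoterWeight + object@bodyGradientWeight > 1)
        return("promoterWeight + bodyGradientWeight must be <= 1")
    if (object@spikeinFraction <= 0 || object@spikeinFraction >= 1)
        return("spikeinFraction must be in (0, 1)")
    if (object@gradientSlope < 0) return("gradientSlope must be >= 0")
    TRUE
})

#' Construct a SignalArchitecture
#'
#' Defaults emulate a wild-type H3K36me3 profile: a strong promoter
#' component, a gene-body component rising 5'->3' (SETD2-like), uniform
#' background, and a 10\% E. coli-like spike-in carried by the Tn5
#' transposome.
#'
#' @param promoterWeight,bodyGradientWeight,spikeinFraction,sigmaProm,gradientSlope,fragLenMean,fragLenSd
#'   see \linkS4class{SignalArchitecture}.
#' @return A \linkS4class{SignalArchitecture}.
#' @examples
#' signalArchitecture(promoterWeight = 0.3)
#' @export
signalArchitecture <- function(promoterWeight = 0.25,
                               bodyGradientWeight = 0.45,
                               spikeinFraction = 0.10,
                               sigmaProm = 150,
                               gradientSlope = 4,
                               fragLenMean = 120,
                               fragLenSd = 25) {
    new("SignalArchitecture",
        promoterWeight = promoterWeight,
        bodyGradientWeight = bodyGradientWeight,
        spikeinFraction = spikeinFraction,
        sigmaProm = sigmaProm,
        gradientSlope = gradientSlope,
        fragLenMean = fragLenMean,
        fragLenSd = fragLenSd)
}

#' PanelDesign: layout of a knockout screening panel
#'
#' One screening round: target genes with per-gene effect multipliers on
#' the promoter component (1 = null, < 1 = true promoter-writer KO,
#' > 1 = gain), grouped into batches each carrying its own wild-type
#' control and a batch-level sequencing-depth multiplier.
#'
#' @slot effects named numeric, KO target -> promoter-weight multiplier.
#' @slot baseDepth fragments per sample before the batch multiplier.
#' @slot batchSize KO samples per batch (each batch adds one WT).
#' @slot depthMultipliers recycled over batches.
#' @slot round screening round label.
#' @aliases PanelDesign
#' @exportClass PanelDesign
setClass("PanelDesign",
    representation(effects = "numeric", baseDepth = "numeric",
                   batchSize = "integer", depthMultipliers = "numeric",
                   round = "integer"))

setValidity("PanelDesign", function(object) {
    if (is.null(names(object@effects)) || anyDuplicated(names(object@effects)))
        return("effects must be uniquely named by KO target gene")
    if (any(object@effects <= 0)) return("effects must be > 0")
    if (object@baseDepth < 1) return("baseDepth must be >= 1")
    if (any(object@depthMultipliers <= 0))
        return("depth multipliers must be > 0")
    TRUE
})

#' Construct a PanelDesign
#'
#' @param effects named numeric vector of promoter-weight multipliers,
#'   one per KO target gene.
#' @param baseDepth fragments per sample before batch depth multipliers.
#' @param batchSize number of KO samples per batch.
#' @param depthMultipliers per-batch depth multipliers, recycled; the
#'   default spans a 4-fold depth range across batches.
#' @param round screening round (1 or 2).
#' @return A \linkS4class{PanelDesign}.
#' @examples
#' panelDesign(c(ko1 = 0.7, ko2 = 1.0))
#' @export
panelDesign <- function(effects, baseDepth = 2e5, batchSize = 5L,
                        depthMultipliers = c(1, 1, 1, 4), round = 1L) {
    new("PanelDesign", effects = effects, baseDepth = baseDepth,
        batchSize = as.integer(batchSize),
        depthMultipliers = depthMultipliers, round = as.integer(round))
}
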