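#' Accessors for promScreen classes
#'
#' Small accessor family: \code{fragments()} returns the GRanges inside a
#' \linkS4class{FragmentSet}; \code{refClass()} its per-fragment reference
#' class; \code{sampleId()} its identifier; \code{binValues()} /
#' \code{binSize()} / \code{trackUnits()} the contents of a
#' \linkS4class{CoverageTrack}; \code{metageneValues()} the matrix inside
#' a \linkS4class{MetageneMatrix}; \code{indexValue()} the ratio inside an
#' \linkS4class{IndexResult}; \code{sfValue()} a
#' \linkS4class{ScaleFactor}'s numeric value.
#'
#' @param x an object of the documented class.
#' @return The accessed component.
#' @name accessors
#' @examples
#' sf <- computeScaleFactor(5e5)
#' sfValue(sf)
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname accessors
#' @export
setGeneric("refClass", function(x) standardGeneric("refClass"))
#' @rdname accessors
#' @export
setMethod("refClass", "FragmentSet",
          function(x) x@fragments$refClass)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))
#' @rdname accessors
#' @export
setMethod("binValues", "CoverageTrack", function(x) x@bins)

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

#' @rdname accessors
#' @export
setGeneric("trackUnits", function(x) standardGeneric("trackUnits"))
#' @rdname accessors
#' @export
setMethod("trackUnits", "CoverageTrack", function(x) x@units)

#' @rdname accessors
#' @export
setGeneric("metageneValues", function(x) standardGeneric("metageneValues"))
#' @rdname accessors
#' @export
setMethod("metageneValues", "MetageneMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
#' @rdname accessors
#' @export
setMethod("indexValue", "IndexResult", function(x) x@index)

#' @rdname accessors
#' @export
setGeneric("sfValue", function(x) standardGeneric("sfValue"))
#' @rdname accessors
#' @export
setMethod("sfValue", "ScaleFactor", function(x) x@value)

setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
    counts <- table(factor(object@fragments$refClass,
                           levels = c("sample", "spikein")))
    cat("FragmentSet '", object@sampleId, "': ",
        length(object@fragments), " fragments (",
        counts[["sample"]], " sample, ", counts[["spikein"]],
        " spike-in) on ", length(object@chromClass),
        " chromosome(s)\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack: ", length(object@bins), " chromosome(s), binSize ",
        object@binSize, ", units '", object@units, "'",
        if (!is.na(object@scaleFactor))
            sprintf(", scaleFactor %.4g", object@scaleFactor) else "",
        "\n", sep = "")
})

setMethod("show", "ScaleFactor", function(object) {
    cat(sprintf("ScaleFactor: %g / %g = %.6g\n", object@constant,
                object@spikeinReads, object@value))
})

setMethod("show", "MetageneMatrix", function(object) {
    cat("MetageneMatrix: ", nrow(object@values), " genes x ",
        ncol(object@values), " scaled positions (flank ", object@flankBp,
        " bp / bin ", object@binSize, " bp, body ", object@bodyBins,
        " bins); ", length(object@excluded), " gene(s) excluded\n",
        sep = "")
})

setMethod("show", "IndexResult", function(object) {
    cat(sprintf(
        "IndexResult '%s': promoter %.4g / gene body %.4g = index %.4g (%d genes%s)\n",
        object@sampleId, object@promoterSignal, object@genebodySignal,
        object@index, object@nGenes,
        if (!is.na(object@batch)) paste0(", batch ", object@batch) else ""))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf(
        "OverlapResult: %d A-peaks, %d B-peaks, %d overlapping; universe %d; OR %.3g; two-sided Fisher P = %.3g\n",
        object@nA, object@nB, object@nOverlap, object@universeSize,
        object@oddsRatio, object@pValue))
})

setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf(
        "CorrelationResult: R = %.3f (n = %d, P = %.3g), fit y = %.4g x + %.4g\n",
        object@r, object@n, object@pValue, object@slope, object@intercept))
})

setMethod("show", "SignalArchitecture", function(object) {
    bg <- 1 - object@promoterWeight - object@bodyGradientWeight
    cat(sprintf(
        "SignalArchitecture: promoter %.2f / body-gradient %.2f / background %.2f; spike-in %.2f; sigmaProm %g bp\n",
        object@promoterWeight, object@bodyGradientWeight, bg,
        object@spikeinFraction, object@sigmaProm))
})

setMethod("show", "PanelDesign", function(object) {
    cat("PanelDesign: ", length(object@effects), " KO targets, batch size ",
        object@batchSize, ", base depth ", object@baseDepth,
        ", round ", object@round, "\n", sep = "")
})
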