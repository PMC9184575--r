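#' The promoter/gene-body H3K36me3 index
#'
#' Index = (normalized signal at TSS +/- \code{halfwidth}) /
#' (normalized signal over the gene body, \code{offset} downstream of
#' the TSS to the TES). By default each aggregate is the mean over
#' eligible genes of the per-gene mean signal density, and the index is
#' the ratio of the two aggregates; \code{aggregate = "perGene"} instead
#' averages per-gene ratios (less stable for low-signal genes). Genes
#' whose body is empty after the offset are excluded.
#'
#' @param track a normalized \linkS4class{CoverageTrack}.
#' @param genes named GRanges of gene models.
#' @param halfwidth promoter half-width in bases (default 500).
#' @param offset gene-body offset downstream of the TSS (default 500).
#' @param aggregate \code{"pooled"} (default) or \code{"perGene"}.
#' @param sampleId,batch labels stored on the result.
#' @param subset optional gene ids to restrict the computation to.
#' @return An \linkS4class{IndexResult}.
#' @export
h3k36me3Index <- function(track, genes, halfwidth = 500, offset = 500,
                          aggregate = c("pooled", "perGene"),
                          sampleId = "sample", batch = NA_character_,
                          subset = NULL) {
    aggregate <- match.arg(aggregate)
    if (!is.null(subset)) genes <- genes[names(genes) %in% subset]
    body <- geneBodyRegions(genes, offset)
    if (!length(body))
        stop("no eligible genes (all bodies empty after the offset)")
    prom <- promoterRegions(genes, halfwidth)[names(body)]
    promMeans <- regionMeanSignal(track, prom)
    bodyMeans <- regionMeanSignal(track, body)
    ps <- mean(promMeans); gs <- mean(bodyMeans)
    if (gs == 0)
        stop("gene-body signal is zero; index undefined on this fixture")
    idx <- if (aggregate == "pooled") ps / gs
           else mean(promMeans / bodyMeans)
    new("IndexResult", sampleId = as.character(sampleId),
        promoterSignal = ps, genebodySignal = gs, index = idx,
        nGenes = length(body), batch = as.character(batch))
}

#' Batch-normalized KO/WT index ratio
#'
#' Divides a knockout sample's index by the same-batch wild-type index,
#' so a ratio of 1 means no promoter-specific change, < 1 lower
#' promoter enrichment, > 1 higher.
#'
#' @param ko,wt \linkS4class{IndexResult}s from the same declared batch
#'   (a batch mismatch is an error; unset batches are not checked).
#' @return single numeric ratio.
#' @export
batchNormalize <- function(ko, wt) {
    if (!is.na(ko@batch) && !is.na(wt@batch) &&
        ko@batch != wt@batch)
        stop(sprintf("batch mismatch: KO '%s' vs WT '%s'",
                     ko@batch, wt@batch))
    if (wt@index <= 0) stop("WT index must be > 0")
    ko@index / wt@index
}

#' Classify an index ratio against the screening threshold
#'
#' With the default 15\% criterion: ratio < 1 - threshold is
#' \code{"decreased"}, ratio > 1 + threshold is \code{"increased"},
#' anything else \code{"unchanged"}. The boundaries are closed on the
#' unchanged side: a ratio of exactly 0.85 or 1.15 is unchanged.
#'
#' @param ratio numeric vector of KO/WT index ratios (> 0).
#' @param threshold fractional change criterion in (0, 1); default 0.15.
#' @return character vector in \{decreased, unchanged, increased\}.
#' @examples
#' classifyChange(c(0.84, 0.85, 1.15, 1.16))
#' @export
classifyChange <- function(ratio, threshold = 0.15) {
    if (any(ratio <= 0)) stop("ratios must be > 0")
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must be in (0, 1)")
    ifelse(ratio < 1 - threshold, "decreased",
           ifelse(ratio > 1 + threshold, "increased", "unchanged"))
}

#' Confirm screen hits across two rounds
#'
#' A gene is a confirmed hit only when both rounds (independent sgRNA
#' clones) yield the same non-unchanged call: \code{hit_decreased},
#' \code{hit_increased}, otherwise \code{not_confirmed}. Round-2 genes
#' must be a subset of round-1 genes; genes not re-screened in round 2
#' are \code{not_confirmed}.
#'
#' @param round1,round2 data.frames with columns \code{gene} and
#'   \code{call} (round 2 may be empty).
#' @return data.frame with columns \code{gene}, \code{call1},
#'   \code{call2}, \code{confirmed}.
#' @export
confirmHits <- function(round1, round2) {
    stopifnot(all(c("gene", "call") %in% names(round1)))
    extra <- setdiff(round2$gene, round1$gene)
    if (length(extra))
        stop("gene(s) in round 2 but not round 1: ",
             paste(extra, collapse = ", "))
    call2 <- setNames(rep(NA_character_, nrow(round1)), round1$gene)
    if (nrow(round2)) call2[round2$gene] <- round2$call
    confirmed <- ifelse(
        !is.na(call2) & call2 == round1$call & round1$call != "unchanged",
        paste0("hit_", round1$call), "not_confirmed")
    data.frame(gene = round1$gene, call1 = round1$call,
               call2 = unname(call2), confirmed = confirmed,
               stringsAsFactors = FALSE)
}

#' Index a panel of samples and call one screening round
#'
#' Computes the H3K36me3 index for every sample of a screening round,
#' normalizes each KO to the wild-type of its batch, and classifies the
#' ratios. Replicate FragmentSets sharing a sample id should be pooled
#' before calling (see \code{\link{poolFragments}}).
#'
#' @param fragmentSets named list of \linkS4class{FragmentSet}s.
#' @param manifest data.frame with columns \code{sample_id},
#'   \code{gene}, \code{batch}, \code{round}, \code{role} (WT/KO);
#'   sample_id keys into \code{fragmentSets}.
#' @param genes named GRanges of gene models.
#' @param binSize,constant,spikein coverage parameters (see
#'   \code{\link{normalizedCoverage}}).
#' @param halfwidth,offset,aggregate index parameters (see
#'   \code{\link{h3k36me3Index}}).
#' @param threshold screening criterion (see
#'   \code{\link{classifyChange}}).
#' @return list with \code{indices} (per-sample data.frame) and
#'   \code{calls} (per-KO-gene data.frame: gene, batch, round, wtIndex,
#'   koIndex, ratio, call).
#' @export
screenRound <- function(fragmentSets, manifest, genes, binSize = 50L,
                        constant = 1e6, spikein = TRUE, halfwidth = 500,
                        offset = 500, aggregate = "pooled",
                        threshold = 0.15) {
    need <- c("sample_id", "gene", "batch", "round", "role")
    if (!all(need %in% names(manifest)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(manifest$sample_id, names(fragmentSets))
    if (length(missing))
        stop("manifest sample(s) without fragments: ",
             paste(missing, collapse = ", "))
    indices <- lapply(seq_len(nrow(manifest)), function(i) {
        row <- manifest[i, ]
        tr <- normalizedCoverage(fragmentSets[[row$sample_id]],
                                 binSize = binSize, constant = constant,
                                 spikein = spikein)
        h3k36me3Index(tr, genes, halfwidth = halfwidth, offset = offset,
                      aggregate = aggregate, sampleId = row$sample_id,
                      batch = row$batch)
    })
    idxTab <- data.frame(
        sample_id = manifest$sample_id, gene = manifest$gene,
        batch = manifest$batch, round = manifest$round,
        role = manifest$role,
        promoter_signal = vapply(indices, slot, numeric(1),
                                 "promoterSignal"),
        genebody_signal = vapply(indices, slot, numeric(1),
                                 "genebodySignal"),
        index = vapply(indices, indexValue, numeric(1)),
        n_genes = vapply(indices, slot, integer(1), "nGenes"),
        stringsAsFactors = FALSE)
    calls <- do.call(rbind, lapply(split(idxTab, idxTab$batch),
                                   function(b) {
        wt <- b[b$role == "WT", ]
        if (nrow(wt) != 1L)
            stop("batch '", b$batch[1],
                 "' must contain exactly one WT sample")
        ko <- b[b$role == "KO", ]
        if (!nrow(ko)) return(NULL)
        ratio <- ko$index / wt$index
        data.frame(gene = ko$gene, batch = ko$batch, round = ko$round,
                   wtIndex = wt$index, koIndex = ko$index, ratio = ratio,
                   call = classifyChange(ratio, threshold),
                   stringsAsFactors = FALSE)
    }))
    rownames(calls) <- NULL
    list(indices = idxTab, calls = calls[order(calls$gene), ])
}

#' Pool replicate fragment sets
#'
#' Merges the fragments of replicates into one set (replicates are
#' merged before indexing), keeping the chromosome-class map of the
#' first.
#'
#' @param ... \linkS4class{FragmentSet}s (or one list of them).
#' @param sampleId identifier for the pooled set.
#' @return A \linkS4class{FragmentSet}.
#' @export
poolFragments <- function(..., sampleId = "pooled") {
    sets <- list(...)
    if (length(sets) == 1L && is.list(sets[[1]]) &&
        !is(sets[[1]], "FragmentSet"))
        sets <- sets[[1]]
    grl <- lapply(sets, fragments)
    gr <- do.call(c, lapply(grl, function(g) { g$refClass <- NULL; g }))
    FragmentSet(gr, chromClass = sets[[1]]@chromClass,
                sampleId = sampleId)
}
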