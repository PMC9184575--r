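#' Read gene models from BED6 or a gene TSV
#'
#' Accepts either BED6 (chrom, start, end, name, score, strand; 0-based
#' half-open) or a 5/6-column gene table (gene_id, chrom, start, end,
#' strand[, length]) with the same 0-based half-open coordinates. Returns
#' a named GRanges whose strand determines the transcription start site
#' (TSS = BED start on +, BED end on -) and transcription end site (the
#' opposite terminus).
#'
#' @param path annotation file (tab-separated).
#' @param chromSizes optional named vector of chromosome lengths; when
#'   given, seqlengths are set and out-of-bounds genes are an error.
#' @return GRanges named by gene id.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t5000\tgeneA\t0\t+", p)
#' readGeneModels(p, c(chr1 = 10000))
#' @export
readGeneModels <- function(path, chromSizes = NULL) {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    lineNo <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (!length(fields)) stop("no gene records in ", path)
    nf <- lengths(fields)
    .bad <- function(i, why)
        stop(sprintf("parse error at line %d of %s: %s", lineNo[i], path, why))
    isStrand <- function(x) x %in% c("+", "-")
    f1 <- fields[[1]]
    if (length(f1) >= 6 && isStrand(f1[6])) {
        fmt <- "bed6"; need <- 6L
    } else if (length(f1) >= 5 && isStrand(f1[5])) {
        fmt <- "tsv"; need <- 5L
    } else stop("unrecognized gene annotation format in ", path,
                " (expected BED6 or gene_id/chrom/start/end/strand TSV)")
    short <- which(nf < need)
    if (length(short)) .bad(short[1], sprintf("expected >= %d fields", need))
    get <- function(k) vapply(fields, `[[`, character(1), k)
    if (fmt == "bed6") {
        chrom <- get(1); s <- get(2); e <- get(3); id <- get(4); str <- get(6)
    } else {
        id <- get(1); chrom <- get(2); s <- get(3); e <- get(4); str <- get(5)
    }
    start0 <- suppressWarnings(as.numeric(s))
    end0 <- suppressWarnings(as.numeric(e))
    badNum <- which(is.na(start0) | is.na(end0))
    if (length(badNum)) .bad(badNum[1], "non-numeric coordinate")
    badStr <- which(!isStrand(str))
    if (length(badStr))
        .bad(badStr[1], sprintf("strand '%s' not in {+,-}", str[badStr[1]]))
    badOrd <- which(start0 >= end0)
    if (length(badOrd)) .bad(badOrd[1], "start must be < end")
    dup <- which(duplicated(id))
    if (length(dup))
        .bad(dup[1], sprintf("duplicate gene_id '%s'", id[dup[1]]))
    gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = str)
    names(gr) <- id
    if (!is.null(chromSizes)) {
        unknown <- setdiff(as.character(seqnames(gr)), names(chromSizes))
        if (length(unknown))
            stop("gene(s) on chromosome(s) absent from chromSizes: ",
                 paste(unique(unknown), collapse = ", "))
        seqlevels(gr) <- names(chromSizes)
        seqlengths(gr) <- chromSizes
        over <- which(end(gr) > chromSizes[as.character(seqnames(gr))])
        if (length(over)) .bad(over[1], "gene end exceeds chromosome length")
    }
    gr
}

#' Write gene models as BED6
#'
#' @param genes named GRanges as returned by \code{\link{readGeneModels}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
    df <- data.frame(chrom = as.character(seqnames(genes)),
                     start = start(genes) - 1L, end = end(genes),
                     name = names(genes), score = 0L,
                     strand = as.character(strand(genes)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Transcription start / end sites (0-based)
#'
#' 0-based half-open convention: for a gene occupying [start0, end0), the
#' TSS is start0 on the + strand and end0 on the - strand; the TES is the
#' opposite terminus.
#'
#' @param genes named GRanges.
#' @return named numeric vector of 0-based positions.
#' @export
tssPositions <- function(genes) {
    pos <- ifelse(as.character(strand(genes)) == "-",
                  end(genes), start(genes) - 1L)
    setNames(as.numeric(pos), names(genes))
}

#' @rdname tssPositions
#' @export
tesPositions <- function(genes) {
    pos <- ifelse(as.character(strand(genes)) == "-",
                  start(genes) - 1L, end(genes))
    setNames(as.numeric(pos), names(genes))
}

#' Promoter regions: a symmetric window around the TSS
#'
#' The promoter of a gene is the window TSS +/- \code{halfwidth} (0-based
#' half-open [tss - halfwidth, tss + halfwidth)), strand-independent in
#' span, clipped at chromosome boundaries when seqlengths are known.
#'
#' @param genes named GRanges.
#' @param halfwidth bases on each side of the TSS (default 500).
#' @return named GRanges of promoter windows (role "promoter").
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000), "+")
#' names(gr) <- "geneA"
#' promoterRegions(gr)   # 0-based [500, 1500)
#' @export
promoterRegions <- function(genes, halfwidth = 500) {
    if (halfwidth <= 0) stop("halfwidth must be > 0")
    tss0 <- tssPositions(genes)
    s0 <- pmax(tss0 - halfwidth, 0)
    e0 <- tss0 + halfwidth
    sl <- seqlengths(genes)[as.character(seqnames(genes))]
    e0 <- ifelse(is.na(sl), e0, pmin(e0, sl))
    out <- GRanges(seqnames(genes), IRanges(s0 + 1, e0),
                   strand = strand(genes), role = "promoter")
    names(out) <- names(genes)
    seqlevels(out) <- seqlevels(genes)
    seqlengths(out) <- seqlengths(genes)
    out
}

#' Gene-body regions: offset downstream of the TSS to the TES
#'
#' Strand-aware: on the + strand [tss + offset, tes), on the - strand
#' [tes, tss - offset) (0-based half-open). Genes whose body would be
#' empty (TES within \code{offset} of the TSS) are dropped; callers can
#' compare names to find the exclusions.
#'
#' @param genes named GRanges.
#' @param offset bases skipped downstream of the TSS (default 500).
#' @return named GRanges of gene-body windows (role "genebody"), possibly
#'   shorter than \code{genes}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000), "+")
#' names(gr) <- "geneA"
#' geneBodyRegions(gr)   # 0-based [1500, 5000)
#' @export
geneBodyRegions <- function(genes, offset = 500) {
    minus <- as.character(strand(genes)) == "-"
    tss0 <- tssPositions(genes)
    tes0 <- tesPositions(genes)
    s0 <- ifelse(minus, tes0, tss0 + offset)
    e0 <- ifelse(minus, tss0 - offset, tes0)
    keep <- e0 - s0 > 0
    out <- GRanges(seqnames(genes)[keep], IRanges(s0[keep] + 1, e0[keep]),
                   strand = strand(genes)[keep], role = "genebody")
    names(out) <- names(genes)[keep]
    seqlevels(out) <- seqlevels(genes)
    seqlengths(out) <- seqlengths(genes)
    out
}

#' Read / write fragment intervals (BED3)
#'
#' Fragments are stored as BED3 (0-based half-open). On reading, every
#' interval is validated against the declared chromosome sizes and
#' labeled \code{"sample"} or \code{"spikein"} from the chromosome ->
#' reference-class map -- the class is never inferred from coordinates.
#'
#' @param path BED3(+) file of fragment intervals.
#' @param chromSizes named vector of chromosome lengths.
#' @param chromClass named character vector chromosome -> class
#'   (\code{"sample"} / \code{"spikein"}).
#' @param sampleId identifier for the resulting set.
#' @return A \linkS4class{FragmentSet}.
#' @export
readFragments <- function(path, chromSizes, chromClass,
                          sampleId = basename(path)) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 3) stop("BED3 input required in ", path)
    chrom <- as.character(df[[1]])
    start0 <- as.numeric(df[[2]]); end0 <- as.numeric(df[[3]])
    if (anyNA(start0) || anyNA(end0))
        stop("non-numeric coordinates in ", path)
    bad <- which(end0 <= start0)
    if (length(bad))
        stop(sprintf("fragment end <= start at record %d of %s",
                     bad[1], path))
    unknown <- setdiff(chrom, names(chromSizes))
    if (length(unknown))
        stop("fragment(s) on chromosome(s) absent from chromSizes: ",
             paste(unique(unknown), collapse = ", "))
    over <- which(end0 > chromSizes[chrom] | start0 < 0)
    if (length(over))
        stop(sprintf(
            "fragment exceeds chromosome bounds at record %d of %s",
            over[1], path))
    gr <- GRanges(factor(chrom, levels = names(chromSizes)),
                  IRanges(start0 + 1, end0))
    FragmentSet(gr, chromClass = chromClass, sampleId = sampleId,
                chromSizes = chromSizes)
}

#' @rdname readFragments
#' @param fs a \linkS4class{FragmentSet} to write.
#' @export
writeFragments <- function(fs, path) {
    gr <- fragments(fs)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write chromosome sizes and reference-class maps
#'
#' Chromosome sizes are a two-column TSV (chrom, length); the
#' reference-class map is a two-column TSV (chrom, sample|spikein).
#'
#' @param path input file.
#' @return Named numeric (sizes) or named character (classes).
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    sizes <- as.numeric(df[[2]])
    if (anyNA(sizes) || any(sizes <= 0))
        stop("invalid chromosome length in ", path)
    setNames(sizes, as.character(df[[1]]))
}

#' @rdname readChromSizes
#' @export
readRefClassMap <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    cls <- as.character(df[[2]])
    if (!all(cls %in% c("sample", "spikein")))
        stop("reference classes must be 'sample' or 'spikein' in ", path)
    setNames(cls, as.character(df[[1]]))
}

#' @rdname readChromSizes
#' @param x named vector to write (sizes or classes).
#' @export
writeChromSizes <- function(x, path) {
    write.table(data.frame(names(x), unname(x)), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}
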