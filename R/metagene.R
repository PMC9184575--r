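# Cell boundaries of one gene's scale-regions row, on the genomic axis,
# ordered 5'->3' (descending for minus-strand genes). nf flank cells of
# width binSize, bodyBins equal subdivisions of [TSS, TES), nf more
# flank cells.
.metageneBoundaries <- function(s0, e0, minus, flankBp, binSize,
                                bodyBins) {
    nf <- flankBp %/% binSize
    len <- e0 - s0
    if (!minus) {
        c(s0 - flankBp + binSize * (0:nf),
          s0 + len * (seq_len(bodyBins - 1)) / bodyBins,
          e0 + binSize * (0:nf))
    } else {
        c(e0 + flankBp - binSize * (0:nf),
          e0 - len * (seq_len(bodyBins - 1)) / bodyBins,
          s0 - binSize * (0:nf))
    }
}

#' Scale-regions metagene matrix
#'
#' Builds the genes x scaled-position matrix spanning
#' flank--body--flank: \code{flankBp / binSize} fixed-width cells
#' upstream of the TSS, \code{bodyBins} equal genomic subdivisions of
#' [TSS, TES), and the downstream flank, each cell holding the mean
#' signal density over its span (so profiles are comparable across genes
#' of different lengths). Rows are oriented 5' to 3'; minus-strand rows
#' are reversed genomic order. Genes shorter than \code{bodyBins} bases
#' still receive \code{bodyBins} cells through fractional-bin averaging.
#' Flank parts beyond a chromosome end count as zero signal.
#'
#' @param track a \linkS4class{CoverageTrack} (normally normalized).
#' @param genes named GRanges of gene models.
#' @param flankBp flank extent in bases (default 5000); must be a
#'   multiple of the track bin size.
#' @param bodyBins number of body subdivisions (default 100).
#' @param minGeneLength genes shorter than this are excluded (recorded
#'   in the object's \code{excluded} slot).
#' @return A \linkS4class{MetageneMatrix}.
#' @export
buildMetageneMatrix <- function(track, genes, flankBp = 5000L,
                                bodyBins = 100L, minGeneLength = 0L) {
    flankBp <- as.integer(flankBp); bodyBins <- as.integer(bodyBins)
    bs <- binSize(track)
    if (flankBp %% bs != 0L)
        stop("flankBp must be a multiple of the track bin size")
    if (is.null(names(genes)) || anyDuplicated(names(genes)))
        stop("genes must be uniquely named")
    widths <- end(genes) - (start(genes) - 1L)
    keep <- widths >= max(minGeneLength, 1L)
    excluded <- names(genes)[!keep]
    genes <- genes[keep]
    if (!length(genes)) stop("no eligible genes for the metagene matrix")
    nf <- flankBp %/% bs
    ncols <- 2L * nf + bodyBins
    chroms <- as.character(seqnames(genes))
    minus <- as.character(strand(genes)) == "-"
    s0 <- start(genes) - 1; e0 <- as.numeric(end(genes))
    mat <- matrix(NA_real_, nrow = length(genes), ncol = ncols,
                  dimnames = list(names(genes), NULL))
    for (chr in unique(chroms)) {
        S <- .cumSignalEvaluator(track, chr)
        for (i in which(chroms == chr)) {
            b <- .metageneBoundaries(s0[i], e0[i], minus[i], flankBp,
                                     bs, bodyBins)
            mat[i, ] <- diff(S(b)) / diff(b)
        }
    }
    colnames(mat) <- c(paste0("up", seq_len(nf)),
                       paste0("body", seq_len(bodyBins)),
                       paste0("down", seq_len(nf)))
    new("MetageneMatrix", values = mat, flankBp = flankBp,
        binSize = bs, bodyBins = bodyBins, excluded = excluded)
}

#' Average metagene profile
#'
#' Column-wise arithmetic mean over a subset of genes (all by default),
#' optionally with the standard error of the mean.
#'
#' @param m a \linkS4class{MetageneMatrix}.
#' @param subset gene ids to average over (default: all rows).
#' @param sem also return the per-column SEM.
#' @return numeric profile vector, or a data.frame with columns
#'   \code{mean} and \code{sem} when \code{sem = TRUE}.
#' @export
averageProfile <- function(m, subset = NULL, sem = FALSE) {
    vals <- metageneValues(m)
    if (!is.null(subset)) {
        if (!length(subset)) stop("empty gene subset")
        missing <- setdiff(subset, rownames(vals))
        if (length(missing))
            stop("subset gene(s) not in matrix: ",
                 paste(head(missing, 5), collapse = ", "))
        vals <- vals[subset, , drop = FALSE]
    }
    mu <- colMeans(vals)
    if (!sem) return(mu)
    s <- apply(vals, 2, sd) / sqrt(nrow(vals))
    data.frame(mean = mu, sem = s, row.names = colnames(vals))
}

#' Expression-grouped metagene profiles
#'
#' Splits genes into high (top 25\% of expression), low (bottom 25\%)
#' and medium (remainder) groups and averages each group's rows. Ranking
#' is ascending by expression with ties broken by gene id (stable,
#' documented): with n genes, the bottom floor(n/4) ranks are "low" and
#' the top floor(n/4) are "high".
#'
#' @param m a \linkS4class{MetageneMatrix}.
#' @param expression named numeric vector of expression values; at least
#'   4 genes must be shared with the matrix rows.
#' @return list with profile vectors \code{high}, \code{medium},
#'   \code{low} and a factor \code{groups} naming each gene's group.
#' @export
groupedProfiles <- function(m, expression) {
    ids <- intersect(rownames(metageneValues(m)), names(expression))
    n <- length(ids)
    if (n < 4) stop("expression must cover at least 4 genes in the matrix")
    expr <- expression[ids]
    ord <- ids[order(expr, ids)]
    k <- n %/% 4L
    low <- ord[seq_len(k)]
    high <- ord[seq.int(n - k + 1L, n)]
    medium <- setdiff(ord, c(low, high))
    groups <- factor(setNames(rep("medium", n), ord),
                     levels = c("high", "medium", "low"))
    groups[low] <- "low"; groups[high] <- "high"
    list(high = averageProfile(m, high),
         medium = averageProfile(m, medium),
         low = averageProfile(m, low),
         groups = groups)
}

#' Write / read a metagene matrix as annotated TSV
#'
#' The matrix is written as gene_id + columns TSV preceded by one JSON
#' header comment line carrying the scale-regions metadata, so a file
#' round-trips into an identical object.
#'
#' @param m a \linkS4class{MetageneMatrix}.
#' @param path output TSV.
#' @return \code{writeMetageneMatrix}: \code{path}, invisibly;
#'   \code{readMetageneMatrix}: a \linkS4class{MetageneMatrix}.
#' @export
writeMetageneMatrix <- function(m, path) {
    meta <- jsonlite::toJSON(list(flank_bp = m@flankBp,
                                  binsize = m@binSize,
                                  body_bins = m@bodyBins,
                                  excluded = m@excluded),
                             auto_unbox = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", meta), con)
    df <- data.frame(gene_id = rownames(m@values), m@values,
                     check.names = FALSE)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    invisible(path)
}

#' @rdname writeMetageneMatrix
#' @export
readMetageneMatrix <- function(path) {
    header <- readLines(path, n = 1L)
    if (!startsWith(header, "#"))
        stop("missing JSON metadata header in ", path)
    meta <- jsonlite::fromJSON(sub("^#", "", header))
    df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE, stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    new("MetageneMatrix", values = mat,
        flankBp = as.integer(meta$flank_bp),
        binSize = as.integer(meta$binsize),
        bodyBins = as.integer(meta$body_bins),
        excluded = as.character(unlist(meta$excluded)))
}
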