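#' RPKM normalization
#'
#' Reads per kilobase of gene per million mapped reads:
#' count / (length_kb * library_size_millions), computed per column.
#'
#' @param counts gene x sample count matrix (rownames = gene ids).
#' @param lengths named numeric gene lengths in bases (> 0), covering
#'   all rows.
#' @return matrix of RPKM values, same shape as \code{counts}.
#' @examples
#' m <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
#' rpkm(m, c(g1 = 1000)) / (10 / (1 * 10 / 1e6))  # unit case
#' @export
rpkm <- function(counts, lengths) {
    counts <- as.matrix(counts)
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing))
        stop("length missing for gene(s): ",
             paste(head(missing, 5), collapse = ", "))
    len <- lengths[rownames(counts)]
    if (any(len <= 0)) stop("gene lengths must be > 0")
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("zero library size in counts")
    sweep(counts / (len / 1000), 2, lib / 1e6, "/")
}

#' Differential expression by log-RPKM t-tests
#'
#' A deliberately simple differential test feeding the correlation
#' stages: log2 fold change of mean RPKM (with pseudocount), a
#' two-sided pooled-variance two-sample t-test on
#' log2(RPKM + pseudocount) between conditions (the classical Student
#' test; with 2-3 replicates per group the pooled estimate keeps the
#' test calibrated where Welch's small-sample df correction is overly
#' conservative), and a direction call -- \code{up} iff log2FC > \code{lfcThreshold} and
#' P < \code{alpha} (strict inequalities), \code{down} for the mirror,
#' otherwise \code{ns}. No negative-binomial modeling is attempted.
#'
#' @param wt,ko replicate count matrices (>= 2 columns each) with
#'   identical rownames.
#' @param lengths named gene lengths in bases (for RPKM).
#' @param pseudocount added before logs (default 1).
#' @param lfcThreshold absolute log2 fold-change cutoff (default 0.5).
#' @param alpha p-value cutoff (default 0.05).
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{p_value}, \code{direction}.
#' @export
deGenes <- function(wt, ko, lengths, pseudocount = 1,
                    lfcThreshold = 0.5, alpha = 0.05) {
    wt <- as.matrix(wt); ko <- as.matrix(ko)
    if (!identical(sort(rownames(wt)), sort(rownames(ko))))
        stop("gene sets differ between conditions")
    ko <- ko[rownames(wt), , drop = FALSE]
    if (ncol(wt) < 2 || ncol(ko) < 2)
        stop("need >= 2 replicates per condition")
    rwt <- rpkm(wt, lengths); rko <- rpkm(ko, lengths)
    log2fc <- log2((rowMeans(rko) + pseudocount) /
                   (rowMeans(rwt) + pseudocount))
    lwt <- log2(rwt + pseudocount); lko <- log2(rko + pseudocount)
    p <- vapply(seq_len(nrow(wt)), function(i) {
        if (sd(lwt[i, ]) == 0 && sd(lko[i, ]) == 0)
            return(if (mean(lko[i, ]) == mean(lwt[i, ])) 1 else 0)
        t.test(lko[i, ], lwt[i, ], alternative = "two.sided",
               var.equal = TRUE)$p.value
    }, numeric(1))
    direction <- ifelse(p < alpha & log2fc > lfcThreshold, "up",
                 ifelse(p < alpha & log2fc < -lfcThreshold, "down",
                        "ns"))
    data.frame(gene = rownames(wt), log2fc = unname(log2fc),
               p_value = p, direction = direction,
               stringsAsFactors = FALSE, row.names = NULL)
}
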