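Package: promScreen
Title: Spike-In-Normalized CUT&Tag Coverage and Promoter H3K36me3 Index
    Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies promoter-localized H3K36me3 from CUT&Tag-like
    fragment data. Provides exogenous spike-in normalization of binned
    genome coverage (reference-adjusted reads per million), scale-regions
    metagene matrices and average profiles, a promoter/gene-body
    enrichment index with a two-round +/-15 percent knockout screening
    rule, a transparent quantile-threshold peak caller with Fisher
    overlap tests, signal-expression correlation and regression analyses,
    RPKM-based differential expression calls, and a synthetic fragment
    and expression generator with known ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, Coverage, ChIPSeq, FunctionalGenomics
RoxygenNote: 7.3.3
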