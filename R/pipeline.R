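.configDefaults <- function() {
    list(binsize = 50, constant = 1e6, threshold = 0.15,
         flank_bp = 5000, body_bins = 100, promoter_halfwidth = 500,
         body_offset = 500, spikein = 1, seed = 1,
         genes = NA_character_, chrom_sizes = NA_character_,
         ref_class_map = NA_character_)
}

#' Read a flat key = value configuration file
#'
#' Defaults mirror the published analysis parameters (500 bp promoter
#' halfwidth, 15\% screening threshold, 5 kb flanks, 1e6 spike-in
#' constant, 50 bp bins); every key is overridable and unknown keys are
#' an error.
#'
#' @param path config file with \code{key = value} lines (\code{#}
#'   comments allowed), or NULL for pure defaults.
#' @return named list of parameters.
#' @export
readConfig <- function(path = NULL) {
    cfg <- .configDefaults()
    if (is.null(path)) return(cfg)
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2)
            stop("malformed config line: '", ln, "'")
        key <- trimws(kv[1]); val <- trimws(kv[2])
        if (!key %in% names(cfg))
            stop("unknown config key: '", key, "'")
        num <- suppressWarnings(as.numeric(val))
        cfg[[key]] <- if (is.na(num)) val else num
    }
    cfg
}

#' Read and validate a screening manifest
#'
#' Tab-separated with header columns sample_id, gene, batch, round,
#' role, fragments (path to the sample's BED file). Duplicate
#' (gene, batch, round, role) combinations and missing fragment files
#' are row-level errors.
#'
#' @param path manifest TSV.
#' @param checkPaths verify that fragment files exist.
#' @return data.frame.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
    mf <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, comment.char = "#")
    need <- c("sample_id", "gene", "batch", "round", "role",
              "fragments")
    missing <- setdiff(need, names(mf))
    if (length(missing))
        stop("manifest missing column(s): ",
             paste(missing, collapse = ", "))
    if (!all(mf$role %in% c("WT", "KO")))
        stop("manifest row ",
             which(!mf$role %in% c("WT", "KO"))[1],
             ": role must be WT or KO")
    key <- paste(mf$gene, mf$batch, mf$round, mf$role)
    if (anyDuplicated(key))
        stop("manifest row ", which(duplicated(key))[1],
             ": duplicate (gene, batch, round, role) combination")
    if (checkPaths) {
        gone <- which(!file.exists(mf$fragments))
        if (length(gone))
            stop("manifest row ", gone[1], ": fragment file not found: ",
                 mf$fragments[gone[1]])
    }
    mf
}

# Provenance header written atop every output table.
.provenanceHeader <- function(cfg, configPath = NULL) {
    hash <- if (!is.null(configPath) && file.exists(configPath))
        unname(md5sum(configPath)) else "defaults"
    c(sprintf("# promScreen %s", as.character(packageVersion("promScreen"))),
      sprintf("# config_md5 %s", hash),
      sprintf("# seed %s", format(cfg$seed)))
}

.writeTableWithHeader <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    invisible(path)
}

#' Write a simulated screening study to disk
#'
#' Materializes a simulated panel as the file layout the pipeline
#' consumes: per-sample fragment BEDs, gene BED, chromosome sizes,
#' reference-class map, manifest, truth table and a config file.
#'
#' @param panel result of \code{\link{simulateKoPanel}}.
#' @param genes,chromSizes,chromClass genome.
#' @param dir output directory (created).
#' @param cfg configuration list (see \code{\link{readConfig}}).
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(panel, genes, chromSizes, chromClass, dir,
                       cfg = readConfig()) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeGeneModels(genes, file.path(dir, "genes.bed"))
    writeChromSizes(chromSizes, file.path(dir, "chrom.sizes"))
    writeChromSizes(chromClass, file.path(dir, "ref_class_map.tsv"))
    fragDir <- file.path(dir, "fragments")
    dir.create(fragDir, showWarnings = FALSE)
    paths <- vapply(names(panel$fragments), function(id) {
        p <- file.path(fragDir, paste0(id, ".bed"))
        writeFragments(panel$fragments[[id]], p)
        p
    }, character(1))
    mf <- panel$manifest
    mf$fragments <- unname(paths[mf$sample_id])
    write.table(mf, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg$genes <- file.path(dir, "genes.bed")
    cfg$chrom_sizes <- file.path(dir, "chrom.sizes")
    cfg$ref_class_map <- file.path(dir, "ref_class_map.tsv")
    writeLines(sprintf("%s = %s", names(cfg),
                       vapply(cfg, format, character(1),
                              scientific = FALSE)),
               file.path(dir, "config.txt"))
    invisible(file.path(dir, "manifest.tsv"))
}

#' Run the screening pipeline from a manifest
#'
#' Stages run in dependency order: \code{coverage} (per-sample
#' spike-in-normalized bedGraph + scale-factor log) then \code{screen}
#' (per-sample index table, per-round screening calls, and when both
#' rounds are present a confirmed-hit table). Every output table
#' carries a provenance header (package version, config hash, seed).
#' Completed stages are skipped unless \code{force}; a re-run with the
#' same inputs reproduces identical tables.
#'
#' @param manifestPath manifest TSV (see \code{\link{readManifest}}).
#' @param configPath optional config file (see
#'   \code{\link{readConfig}}).
#' @param outDir output directory.
#' @param stages subset of \code{c("coverage", "screen")}.
#' @param force re-run stages whose outputs already exist.
#' @return \code{outDir}, invisibly.
#' @export
runPipeline <- function(manifestPath, configPath = NULL, outDir,
                        stages = c("coverage", "screen"),
                        force = FALSE) {
    stages <- match.arg(stages, several.ok = TRUE)
    cfg <- readConfig(configPath)
    for (key in c("genes", "chrom_sizes", "ref_class_map"))
        if (is.na(cfg[[key]]))
            stop("config must provide '", key, "'")
    mf <- readManifest(manifestPath)
    chromSizes <- readChromSizes(cfg$chrom_sizes)
    chromClass <- readRefClassMap(cfg$ref_class_map)
    genes <- readGeneModels(cfg$genes, chromSizes)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    header <- .provenanceHeader(cfg, configPath)
    loadSets <- function() {
        sets <- lapply(seq_len(nrow(mf)), function(i)
            readFragments(mf$fragments[i], chromSizes, chromClass,
                          sampleId = mf$sample_id[i]))
        setNames(sets, mf$sample_id)
    }
    sets <- NULL
    if ("coverage" %in% stages) {
        covDir <- file.path(outDir, "coverage")
        sfPath <- file.path(outDir, "scale_factors.tsv")
        if (force || !file.exists(sfPath)) {
            dir.create(covDir, showWarnings = FALSE)
            sets <- loadSets()
            sfRows <- lapply(names(sets), function(id) {
                counts <- countByRefClass(sets[[id]])
                denom <- if (cfg$spikein != 0) counts[["spikein"]]
                         else counts[["sample"]]
                sf <- computeScaleFactor(denom, cfg$constant)
                tr <- normalizeTrack(
                    fragmentsToCoverage(sets[[id]], cfg$binsize), sf)
                writeBedGraph(tr, file.path(covDir,
                                            paste0(id, ".bedgraph")))
                data.frame(sample_id = id,
                           sample_reads = counts[["sample"]],
                           spikein_reads = counts[["spikein"]],
                           spikein_pct = 100 * counts[["spikein"]] /
                               sum(counts),
                           scale_factor = sfValue(sf))
            })
            .writeTableWithHeader(do.call(rbind, sfRows), sfPath,
                                  header)
        } else message("coverage stage up to date; skipping")
    }
    if ("screen" %in% stages) {
        callsPath <- file.path(outDir, "screen_calls.tsv")
        if (force || !file.exists(callsPath)) {
            if (!file.exists(file.path(outDir, "scale_factors.tsv")))
                stop("screen stage requires the coverage stage outputs")
            if (is.null(sets)) sets <- loadSets()
            allCalls <- list(); allIdx <- list()
            for (rd in sort(unique(mf$round))) {
                sub <- mf[mf$round == rd, ]
                res <- screenRound(sets[sub$sample_id], sub, genes,
                                   binSize = cfg$binsize,
                                   constant = cfg$constant,
                                   spikein = cfg$spikein != 0,
                                   halfwidth = cfg$promoter_halfwidth,
                                   offset = cfg$body_offset,
                                   threshold = cfg$threshold)
                allCalls[[as.character(rd)]] <- res$calls
                allIdx[[as.character(rd)]] <- res$indices
            }
            calls <- do.call(rbind, allCalls)
            rownames(calls) <- NULL
            .writeTableWithHeader(do.call(rbind, allIdx),
                                  file.path(outDir, "index_table.tsv"),
                                  header)
            .writeTableWithHeader(calls, callsPath, header)
            rounds <- sort(unique(calls$round))
            if (length(rounds) >= 2) {
                hits <- confirmHits(
                    calls[calls$round == rounds[1],
                          c("gene", "call")],
                    calls[calls$round == rounds[2],
                          c("gene", "call")])
                .writeTableWithHeader(hits,
                                      file.path(outDir, "hits.tsv"),
                                      header)
            }
            nAll <- length(genes)
            nElig <- length(geneBodyRegions(genes,
                                            cfg$body_offset))
            message(sprintf(
                "screen: %d samples, %d/%d genes eligible (%d excluded)",
                nrow(mf), nElig, nAll, nAll - nElig))
        } else message("screen stage up to date; skipping")
    }
    invisible(outDir)
}
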