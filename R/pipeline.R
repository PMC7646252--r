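#' Configuration of an end-to-end run
#'
#' Bundles the stage thresholds, seeds, and input/output paths for
#' [runAll()]. With `simulate = TRUE` (the default), the simulation stage
#' generates the reads and truth/whitelist/lineage tables the later stages
#' consume; otherwise `reads`, `cellWhitelist` and `lineages` must point at
#' existing files.
#'
#' @param outDir output directory.
#' @param seed top-level seed; each stage derives a named substream.
#' @param simulate run the simulation stage.
#' @param simConfig a [SimConfig-class] for the simulation stage.
#' @param design a [CassetteDesign-class].
#' @param reads,cellWhitelist,uciWhitelist,lineages input paths for
#'   real-data mode (ignored when `simulate = TRUE`).
#' @param callParams a [callParams()] list.
#' @param cutoff frequency-filter cutoff.
#' @param sweep also run the cutoff sensitivity sweep.
#' @param groupBy frequency scope, `"pooled"` or `"eb"`.
#' @param nPerm permutations for the enrichment stage.
#' @param link run the linkage stage.
#' @return A named list (class `loxstamp_run_config`).
#' @export
runConfig <- function(outDir, seed = 1L, simulate = TRUE,
                      simConfig = NULL, design = NULL,
                      reads = NULL, cellWhitelist = NULL,
                      uciWhitelist = NULL, lineages = NULL,
                      callParams = loxstamp::callParams(),
                      cutoff = 0.005, sweep = TRUE,
                      groupBy = c("pooled", "eb"),
                      nPerm = 1000L, link = TRUE) {
    groupBy <- match.arg(groupBy)
    if (is.null(design)) design <- cassetteDesign()
    if (simulate && is.null(simConfig)) {
        simConfig <- loxstamp::simConfig(seed = seed)
    }
    structure(list(outDir = outDir, seed = as.integer(seed),
                   simulate = simulate, simConfig = simConfig,
                   design = design, reads = reads,
                   cellWhitelist = cellWhitelist,
                   uciWhitelist = uciWhitelist, lineages = lineages,
                   callParams = callParams, cutoff = cutoff, sweep = sweep,
                   groupBy = groupBy, nPerm = as.integer(nPerm),
                   link = link),
              class = "loxstamp_run_config")
}

#' Run the full pipeline: simulate, call, filter, link
#'
#' Executes the requested stages in order, writes every artefact under
#' `config$outDir`, and finishes with a JSON manifest carrying the
#' thresholds, seeds, package version and an md5 checksum per output file.
#' Identical configuration and seed reproduce byte-identical outputs.
#'
#' @param config a [runConfig()] object.
#' @return The manifest, invisibly.
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "loxstamp_run_config"))
    dir <- config$outDir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    design <- config$design
    outputs <- character(0)

    fail <- function(stage, e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
    }

    ## --- simulate ---------------------------------------------------------
    if (config$simulate) {
        stageLog("simulate", "generating synthetic experiment")
        sim <- tryCatch(simulateExperiment(config$simConfig, design),
                        error = function(e) fail("simulate", e))
        writeSimulation(sim, dir)
        writeBlockReference(design, file.path(dir, "blocks.fa"))
        writeDesign(design, file.path(dir, "design.json"))
        lineagePath <- file.path(dir, "lineages.tsv")
        writeTsv(data.frame(cell_id = sim$truth$cells$cell_id,
                            lineage = sim$truth$cells$lineage,
                            confidence = "high", stringsAsFactors = FALSE),
                 lineagePath)
        readsPath <- file.path(dir, "reads.fastq")
        cellsPath <- file.path(dir, "whitelist_cells.tsv")
        uciPath <- file.path(dir, "whitelist_uci.tsv")
        ebMap <- sim$truth$cells[, c("cell_id", "eb")]
        outputs <- c(outputs, "reads.fastq", "truth_founders.tsv",
                     "truth_cells.tsv", "truth_reads.tsv",
                     "whitelist_cells.tsv", "whitelist_uci.tsv",
                     "lineages.tsv", "blocks.fa", "design.json")
    } else {
        readsPath <- config$reads
        cellsPath <- config$cellWhitelist
        uciPath <- config$uciWhitelist
        lineagePath <- config$lineages
        ebMap <- NULL
        if (is.null(readsPath) || !file.exists(readsPath)) {
            stop("stage 'call' failed: reads FASTQ not found", call. = FALSE)
        }
        if (is.null(cellsPath) || !file.exists(cellsPath)) {
            stop("stage 'call' failed: cell whitelist not found",
                 call. = FALSE)
        }
    }

    ## --- call -------------------------------------------------------------
    stageLog("call", "calling per-cell timestamp barcodes")
    calls <- tryCatch({
        callTimestamps(readsPath, design, cellsPath,
                       uciWhitelist = if (!is.null(uciPath) &&
                                          file.exists(uciPath)) uciPath,
                       params = config$callParams)
    }, error = function(e) fail("call", e))
    if (!is.null(ebMap)) {
        calls$eb <- ebMap$eb[match(calls$cell_id, ebMap$cell_id)]
    }
    writeTsv(calls, file.path(dir, "cell_calls.tsv"))
    outputs <- c(outputs, "cell_calls.tsv")

    ## --- filter -----------------------------------------------------------
    stageLog("filter", "frequency filter at cutoff ", config$cutoff)
    filt <- tryCatch({
        filterHighFrequency(calls, cutoff = config$cutoff,
                            groupBy = config$groupBy)
    }, error = function(e) fail("filter", e))
    writeTsv(filt$retained, file.path(dir, "cell_calls.filtered.tsv"))
    outputs <- c(outputs, "cell_calls.filtered.tsv")
    if (config$sweep) {
        sweep <- tryCatch(frequencySweep(calls, groupBy = config$groupBy),
                          error = function(e) fail("filter", e))
        writeTsv(sweep, file.path(dir, "frequency_report.tsv"))
        outputs <- c(outputs, "frequency_report.tsv")
    }

    ## --- link -------------------------------------------------------------
    if (config$link) {
        if (is.null(lineagePath) || !file.exists(lineagePath)) {
            stop("stage 'link' failed: lineage table not found",
                 call. = FALSE)
        }
        stageLog("link", "building linkage map (", config$nPerm,
                 " permutations)")
        linkOut <- tryCatch({
            annotated <- joinLineages(filt$retained, lineagePath)
            edges <- buildLinkageEdges(annotated)
            mat <- lineageBarcodeMatrix(annotated)
            enr <- withr::with_seed(stageSeed(config$seed, "link"), {
                sharingEnrichment(annotated, nPerm = config$nPerm)
            })
            corr <- if (ncol(mat) >= 2L) lineageCorrelation(mat) else NULL
            list(edges = edges, mat = mat, enr = enr, corr = corr)
        }, error = function(e) fail("link", e))
        writeTsv(linkOut$edges, file.path(dir, "edges.tsv"))
        writeTsv(linkOut$enr, file.path(dir, "enrichment.tsv"))
        outputs <- c(outputs, "edges.tsv", "enrichment.tsv")
        if (!is.null(linkOut$corr)) {
            cc <- data.frame(lineage = rownames(linkOut$corr), linkOut$corr,
                             check.names = FALSE, stringsAsFactors = FALSE)
            writeTsv(cc, file.path(dir, "lineage_correlation.tsv"))
            outputs <- c(outputs, "lineage_correlation.tsv")
        }
    }

    ## --- manifest ---------------------------------------------------------
    files <- file.path(dir, outputs)
    manifest <- list(
        package = "loxstamp",
        version = as.character(utils::packageVersion("loxstamp")),
        seed = config$seed,
        thresholds = list(
            min_reads = config$callParams$minReads,
            max_edits_cell = config$callParams$maxEditsCell,
            block_max_edit_frac = config$callParams$blockMaxEditFrac,
            uci_len_tol = config$callParams$uciLenTol,
            uci_cluster_dist = config$callParams$uciClusterDist,
            cutoff = config$cutoff,
            n_perm = config$nPerm),
        outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                                  outputs))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageLog("run-all", "complete: ", dir)
    invisible(manifest)
}
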