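#' Construct a synthetic-experiment configuration
#'
#' Defaults follow the benchmarked study conditions: roughly 1,000 founder
#' cells per microwell, a library of ~5,000 static UCIs with a mildly skewed
#' abundance distribution, one cassette integration per cell (MOI < 0.1), a
#' mean of 50 reads per cell (just above the >30-read consensus filter), and
#' a 700-2500 bp amplicon purification window. See the package vignette for
#' the rationale behind every default.
#'
#' @param nFounders founder cells (each one integrated cassette).
#' @param uciLibrarySize distinct UCIs in the plasmid library.
#' @param uciSkew log-normal sigma of UCI abundance weights (0 = uniform).
#' @param uciUnique if `TRUE`, founders draw UCIs without replacement.
#' @param inductionTime `"day0"` (ESC stage; all lineages share founders) or
#'   `"day8"` (post-epiblast stage; `committedLineages` are already
#'   committed, so their founders yield only those lineages).
#' @param lineageProportions named numeric over the lineage set, sums to 1.
#' @param committedLineages lineages committed before a day-8 induction.
#' @param expansion cells per founder at harvest.
#' @param cellsSampled cells drawn (without replacement) for sequencing.
#' @param readsPerCell mean sequenced reads per cell.
#' @param readsDispersion negative-binomial size parameter; `Inf` makes the
#'   per-cell read count exactly `readsPerCell`.
#' @param subRate,insRate,delRate per-base substitution/insertion/deletion
#'   rates of the nanopore-like error model.
#' @param truncationProb probability a read is truncated at a uniform
#'   position of the sequenced strand.
#' @param contaminationRate probability a read's embedded cell barcode is
#'   replaced by another sampled cell's barcode.
#' @param ampliconMin,ampliconMax purification window applied to amplicons.
#' @param lambda Poisson mean of Cre events per cassette at induction.
#' @param bias,excisionWeight,inversionWeight recombination-bias model, see
#'   [simulateRecombination()].
#' @param nEBs embryoid bodies cells are split across (frequency scopes).
#' @param seed integer seed; every stage derives a named substream from it.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nFounders = 1000L,
                      uciLibrarySize = 5000L,
                      uciSkew = 0.5,
                      uciUnique = FALSE,
                      inductionTime = c("day0", "day8"),
                      lineageProportions = c(EN = 0.25, S.Ect = 0.20,
                                             MES = 0.25, BP = 0.15,
                                             PGC = 0.15),
                      committedLineages = "PGC",
                      expansion = 8L,
                      cellsSampled = 1000L,
                      readsPerCell = 50,
                      readsDispersion = 50,
                      subRate = 0.02,
                      insRate = 0.03,
                      delRate = 0.04,
                      truncationProb = 0.1,
                      contaminationRate = 0.02,
                      ampliconMin = 700,
                      ampliconMax = 2500,
                      lambda = 3,
                      bias = 0.5,
                      excisionWeight = 1,
                      inversionWeight = 1,
                      nEBs = 1L,
                      seed = 1L) {
    inductionTime <- match.arg(inductionTime)
    new("SimConfig",
        nFounders = as.integer(nFounders),
        uciLibrarySize = as.integer(uciLibrarySize),
        uciSkew = uciSkew,
        uciUnique = uciUnique,
        inductionTime = inductionTime,
        lineageProportions = lineageProportions,
        committedLineages = committedLineages,
        expansion = as.integer(expansion),
        cellsSampled = as.integer(cellsSampled),
        readsPerCell = readsPerCell,
        readsDispersion = readsDispersion,
        subRate = subRate, insRate = insRate, delRate = delRate,
        truncationProb = truncationProb,
        contaminationRate = contaminationRate,
        ampliconMin = ampliconMin, ampliconMax = ampliconMax,
        lambda = lambda, bias = bias,
        excisionWeight = excisionWeight,
        inversionWeight = inversionWeight,
        nEBs = as.integer(nEBs),
        seed = as.integer(seed))
}

#' Draw a UCI plasmid library
#'
#' `size` distinct random 10-mers with log-normal abundance weights
#' (`skew` is the log-sd; 0 gives uniform weights). Weights are normalised
#' to sum to 1.
#'
#' @param size number of distinct UCIs (at most `4^length`).
#' @param skew log-normal sigma of the abundance distribution.
#' @param length UCI length in nt.
#' @return A data.frame with columns `uci` and `weight`.
#' @export
drawUciLibrary <- function(size, skew = 0.5, length = 10L) {
    if (size > 4^length) {
        stop(sprintf("size %d exceeds the %d-mer sequence space (4^%d)",
                     size, length, length))
    }
    uci <- character(0)
    while (length(uci) < size) {
        uci <- unique(c(uci, randomDNA(rep(length, size - length(uci)))))
    }
    w <- stats::rlnorm(size, meanlog = 0, sdlog = skew)
    data.frame(uci = uci, weight = w / sum(w), stringsAsFactors = FALSE)
}

#' Generate a cell-barcode whitelist
#'
#' Random 12-mers kept only if at least `minDist` mismatches from every
#' barcode already accepted, emulating designed plate barcodes.
#'
#' @param n number of barcodes.
#' @param length barcode length (nt).
#' @param minDist minimum pairwise Hamming distance.
#' @return A character vector of `n` distinct barcodes.
#' @export
makeCellBarcodes <- function(n, length = 12L, minDist = 3L) {
    bases <- c("A", "C", "G", "T")
    kept <- matrix(0L, nrow = n, ncol = length)
    k <- 0L
    while (k < n) {
        cand <- sample.int(4L, length, replace = TRUE)
        ok <- k == 0L ||
            min(rowSums(kept[seq_len(k), , drop = FALSE] !=
                        rep(cand, each = k))) >= minDist
        if (ok) {
            k <- k + 1L
            kept[k, ] <- cand
        }
    }
    apply(kept, 1L, function(row) paste(bases[row], collapse = ""))
}

#' Reassign cell barcodes by cross-contamination
#'
#' Each read, independently with probability `rate`, has its cell-of-origin
#' barcode replaced by the barcode of another cell drawn uniformly from the
#' remaining sampled cells.
#'
#' @param cellIds cell id per read (cells of origin).
#' @param cellPool the full vector of sampled cell ids.
#' @param rate contamination probability in `[0, 1)`.
#' @return An integer/character vector parallel to `cellIds`: the cell whose
#'   barcode each read carries.
#' @export
contaminateAssignments <- function(cellIds, cellPool, rate) {
    stopifnot(rate >= 0, rate <= 1)
    assigned <- cellIds
    hit <- stats::runif(length(cellIds)) < rate
    if (any(hit)) {
        if (length(cellPool) < 2L) {
            stop("contamination requires at least two cells")
        }
        repl <- vapply(cellIds[hit], function(cid) {
            sample(cellPool[cellPool != cid], 1L)
        }, cellPool[1])
        assigned[hit] <- repl
    }
    assigned
}

#' Apply nanopore-like noise to reads
#'
#' Per-base substitution (to a different base), single-base insertion after a
#' base, and deletion, each independent; then, with probability
#' `truncationProb`, the read is cut at a position uniform over its length
#' (keeping the 5' prefix of the sequenced strand, so either end of the
#' molecule can be lost depending on strand).
#'
#' @param seqs character vector of reads.
#' @param subRate,insRate,delRate per-base rates in `[0, 1)`.
#' @param truncationProb truncation probability in `[0, 1)`.
#' @return A list with `seq` (mutated reads) and `truncatedAt` (integer cut
#'   position, `NA` when not truncated).
#' @export
mutateReads <- function(seqs, subRate = 0.02, insRate = 0.03, delRate = 0.04,
                        truncationProb = 0) {
    stopifnot(all(c(subRate, insRate, delRate, truncationProb) >= 0),
              all(c(subRate, insRate, delRate, truncationProb) <= 1))
    bases <- c("A", "C", "G", "T")
    out <- character(length(seqs))
    truncatedAt <- rep(NA_integer_, length(seqs))
    for (r in seq_along(seqs)) {
        ch <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
        n <- length(ch)
        if (n == 0L) { out[r] <- ""; next }
        u <- stats::runif(n)
        del <- u < delRate
        sub <- !del & u < delRate + subRate
        if (any(sub)) {
            ch[sub] <- vapply(ch[sub],
                              function(b) sample(setdiff(bases, b), 1L),
                              character(1), USE.NAMES = FALSE)
        }
        ins <- stats::runif(n) < insRate
        if (any(ins)) {
            ch[ins] <- paste0(ch[ins],
                              sample(bases, sum(ins), replace = TRUE))
        }
        ch <- ch[!del]
        read <- paste(ch, collapse = "")
        if (truncationProb > 0 && stats::runif(1) < truncationProb) {
            cut <- sample.int(nchar(read), 1L)
            truncatedAt[r] <- cut
            read <- substr(read, 1L, cut)
        }
        out[r] <- read
    }
    list(seq = out, truncatedAt = truncatedAt)
}

#' Simulate a ground-truthed timestamp-barcoding experiment
#'
#' Founders each receive one UCI (abundance-weighted from the library) and
#' one recombined cassette drawn at the configured induction time. Under a
#' day-0 induction every founder's descendants sample lineages from the
#' global proportions; under a day-8 induction, founders committed to
#' `committedLineages` (e.g. the PGC-like lineage, specified before the
#' induction window) produce only cells of their committed lineage, while
#' the remaining founders produce only the somatic lineages. Founders are
#' expanded, cells sampled, and per-cell amplicon reads rendered with
#' cell-barcode context, cross-contamination, strand sampling, per-base
#' noise and truncation. Amplicons outside the purification window are
#' dropped before sequencing.
#'
#' @param config a [SimConfig-class].
#' @param design a [CassetteDesign-class].
#' @param reads if `FALSE`, only truth tables are generated (no sequences) -
#'   linkage-level analyses need nothing more.
#' @return A list with elements `truth` (list of `founders`, `cells`,
#'   `reads` data.frames), `reads` (named character vector of sequences, or
#'   `NULL`), `uciLibrary`, `cellWhitelist` (data.frame `cell_id`,
#'   `barcode`), `config`, `design`.
#' @export
simulateExperiment <- function(config, design = cassetteDesign(),
                               reads = TRUE) {
    stopifnot(is(config, "SimConfig"), is(design, "CassetteDesign"))
    validObject(config)
    lineages <- names(config@lineageProportions)
    if (length(lineages) == 0L) stop("the lineage set must be non-empty")
    if (config@nFounders < 1L) stop("at least one founder is required")

    ## founders: UCI + recombined cassette + commitment
    fnd <- withr::with_seed(stageSeed(config@seed, "founders"), {
        lib <- drawUciLibrary(config@uciLibrarySize, config@uciSkew,
                              design@uciLength)
        uciIdx <- sample.int(nrow(lib), config@nFounders,
                             replace = !config@uciUnique, prob = lib$weight)
        start <- intactState(design)
        states <- vector("list", config@nFounders)
        pol <- character(config@nFounders)
        for (f in seq_len(config@nFounders)) {
            st <- simulateRecombination(start, lambda = config@lambda,
                                        bias = config@bias,
                                        excisionWeight = config@excisionWeight,
                                        inversionWeight = config@inversionWeight)
            states[[f]] <- st
            pol[f] <- polyloxString(st)
        }
        committed <- rep(NA_character_, config@nFounders)
        if (config@inductionTime == "day8" &&
            length(config@committedLineages)) {
            pCommit <- sum(config@lineageProportions[config@committedLineages])
            isCommitted <- stats::runif(config@nFounders) < pCommit
            if (any(isCommitted)) {
                committed[isCommitted] <- sample(
                    config@committedLineages, sum(isCommitted), replace = TRUE,
                    prob = config@lineageProportions[config@committedLineages])
            }
        }
        list(lib = lib, states = states,
             table = data.frame(founder_id = seq_len(config@nFounders),
                                uci = lib$uci[uciIdx],
                                polylox = pol,
                                committed_lineage = committed,
                                stringsAsFactors = FALSE))
    })
    founders <- fnd$table
    founderStates <- fnd$states
    uciLibrary <- fnd$lib

    ## cells: expansion, sampling, barcodes, lineage labels, EBs
    cells <- withr::with_seed(stageSeed(config@seed, "cells"), {
        pool <- rep(founders$founder_id, each = config@expansion)
        pick <- sort(sample.int(length(pool), config@cellsSampled))
        founder <- pool[pick]
        barcode <- makeCellBarcodes(config@cellsSampled)
        lin <- character(config@cellsSampled)
        if (config@inductionTime == "day0") {
            lin <- sample(lineages, config@cellsSampled, replace = TRUE,
                          prob = config@lineageProportions)
        } else {
            commit <- founders$committed_lineage[founder]
            fixed <- !is.na(commit)
            lin[fixed] <- commit[fixed]
            somatic <- setdiff(lineages, config@committedLineages)
            pSom <- config@lineageProportions[somatic]
            lin[!fixed] <- sample(somatic, sum(!fixed), replace = TRUE,
                                  prob = pSom / sum(pSom))
        }
        data.frame(cell_id = sprintf("cell%04d", seq_len(config@cellsSampled)),
                   barcode = barcode,
                   founder_id = founder,
                   lineage = lin,
                   eb = sprintf("EB%02d", 1L +
                                (seq_len(config@cellsSampled) - 1L) %%
                                config@nEBs),
                   stringsAsFactors = FALSE)
    })

    ## reads
    readTruth <- data.frame(read_id = character(), cell_id = character(),
                            assigned_cell = character(),
                            strand = character(),
                            truncated_at = integer(),
                            stringsAsFactors = FALSE)
    readSeqs <- NULL
    if (reads) {
        res <- withr::with_seed(stageSeed(config@seed, "reads"), {
            cassette <- vapply(seq_len(config@nFounders), function(f) {
                renderSequence(founderStates[[f]], design,
                               uci = founders$uci[f])
            }, character(1))
            ad <- design@adapterSeqs
            amplicon <- function(cellIdx) {
                paste0(ad[["p5"]], ad[["cell_upstream"]],
                       cells$barcode[cellIdx], ad[["cell_downstream"]],
                       cassette[cells$founder_id[cellIdx]], ad[["p3"]])
            }
            ampLen <- nchar(ad[["p5"]]) + 20L + 12L + 24L +
                nchar(cassette)[cells$founder_id] + nchar(ad[["p3"]])
            inWindow <- ampLen >= config@ampliconMin &
                ampLen <= config@ampliconMax
            counts <- if (is.finite(config@readsDispersion)) {
                stats::rnbinom(nrow(cells), mu = config@readsPerCell,
                               size = config@readsDispersion)
            } else {
                rep(as.integer(round(config@readsPerCell)), nrow(cells))
            }
            counts[!inWindow] <- 0L  # purified away before sequencing
            origin <- rep(seq_len(nrow(cells)), counts)
            assigned <- contaminateAssignments(origin, seq_len(nrow(cells)),
                                               config@contaminationRate)
            ## molecule carries the assigned cell's barcode
            mol <- if (length(origin)) {
                paste0(ad[["p5"]], ad[["cell_upstream"]],
                       cells$barcode[assigned], ad[["cell_downstream"]],
                       cassette[cells$founder_id[origin]], ad[["p3"]])
            } else character(0)
            minus <- stats::runif(length(mol)) < 0.5
            if (any(minus)) mol[minus] <- rcomp(mol[minus])
            noisy <- mutateReads(mol, config@subRate, config@insRate,
                                 config@delRate, config@truncationProb)
            list(origin = origin, assigned = assigned,
                 strand = ifelse(minus, "-", "+"),
                 seq = noisy$seq, truncatedAt = noisy$truncatedAt)
        })
        ids <- sprintf("read%06d", seq_along(res$seq))
        readSeqs <- stats::setNames(res$seq, ids)
        readTruth <- data.frame(read_id = ids,
                                cell_id = cells$cell_id[res$origin],
                                assigned_cell = cells$cell_id[res$assigned],
                                strand = res$strand,
                                truncated_at = res$truncatedAt,
                                stringsAsFactors = FALSE)
    }

    list(truth = list(founders = founders, cells = cells, reads = readTruth),
         reads = readSeqs,
         uciLibrary = uciLibrary,
         cellWhitelist = data.frame(cell_id = cells$cell_id,
                                    barcode = cells$barcode,
                                    stringsAsFactors = FALSE),
         config = config,
         design = design)
}

#' Write a simulated experiment to disk
#'
#' Emits `reads.fastq` (uniform placeholder qualities), `truth_founders.tsv`,
#' `truth_cells.tsv`, `truth_reads.tsv`, `whitelist_cells.tsv` and
#' `whitelist_uci.tsv`. Read identifiers carry no truth information.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sim$reads)) {
        writeFastq(sim$reads, file.path(dir, "reads.fastq"))
    }
    writeTsv(sim$truth$founders, file.path(dir, "truth_founders.tsv"))
    writeTsv(sim$truth$cells, file.path(dir, "truth_cells.tsv"))
    writeTsv(sim$truth$reads, file.path(dir, "truth_reads.tsv"))
    writeTsv(sim$cellWhitelist, file.path(dir, "whitelist_cells.tsv"))
    writeTsv(data.frame(uci = sim$uciLibrary$uci, stringsAsFactors = FALSE),
             file.path(dir, "whitelist_uci.tsv"))
    invisible(dir)
}
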