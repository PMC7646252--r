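#' Barcode-calling parameters
#'
#' Thresholds of the read-to-cell-call pipeline. `minReads` follows the
#' ">30 reads" rule (strict inequality, i.e. at least 31). The outlier rule
#' is Tukey's upper fence over the non-top candidate counts when at least 4
#' candidates are present, otherwise a top/second dominance ratio (second of
#' 0 passes). `uciClusterDist` collapses sequencing-error variants of the
#' single true UCI of a cell before counting (0 disables).
#'
#' @param minReads a call needs strictly more supporting reads than this.
#' @param maxEditsCell maximum edit distance of the barcode+downstream-flank
#'   construct for cell assignment.
#' @param blockMaxEditFrac per-block maximum edit distance as a fraction of
#'   block length.
#' @param flankMaxEditFrac as above, for the 20-nt cell-barcode upstream
#'   flank.
#' @param domRatio dominance ratio top/second used with < 4 candidates.
#' @param tukeyK multiplier of the IQR in Tukey's fence.
#' @param uciLenTol accepted deviation of the extracted insert from the UCI
#'   length.
#' @param uciClusterDist edit-distance radius for per-cell UCI error
#'   collapsing.
#' @param fullLengthRule `"any"`: the candidate barcode must be observed
#'   full length in at least one supporting read; `"majority"`: in more than
#'   half of them.
#' @return A named list of parameters.
#' @export
callParams <- function(minReads = 30L, maxEditsCell = 8L,
                       blockMaxEditFrac = 0.25, flankMaxEditFrac = 0.3,
                       domRatio = 3, tukeyK = 1.5, uciLenTol = 2L,
                       uciClusterDist = 3L,
                       fullLengthRule = c("any", "majority")) {
    list(minReads = as.integer(minReads),
         maxEditsCell = as.integer(maxEditsCell),
         blockMaxEditFrac = blockMaxEditFrac,
         flankMaxEditFrac = flankMaxEditFrac,
         domRatio = domRatio, tukeyK = tukeyK,
         uciLenTol = as.integer(uciLenTol),
         uciClusterDist = as.integer(uciClusterDist),
         fullLengthRule = match.arg(fullLengthRule))
}

refAsCharacter <- function(reference) {
    if (is.null(reference)) return(NULL)
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference)) {
        return(readFasta(reference))
    }
    if (is(reference, "DNAStringSet")) {
        return(stats::setNames(as.character(reference), names(reference)))
    }
    stopifnot(is.character(reference), !is.null(names(reference)))
    reference
}

#' Assign a read to a cell barcode
#'
#' Locates the 20-nt upstream cell flank on both strands, then scores every
#' whitelist barcode (with its 24-nt downstream flank) inside the window
#' that follows, under unit-cost edits. The read is assigned to the unique
#' best-scoring cell whose construct distance is at most `maxEdits`; ties or
#' no passing hit give no assignment.
#'
#' @param read a character scalar (one read).
#' @param whitelist data.frame (`cell_id`, `barcode`) or TSV path.
#' @param design a [CassetteDesign-class] supplying the flank sequences.
#' @param maxEdits maximum accepted construct edit distance.
#' @param flankMaxEditFrac maximum edit fraction when locating the upstream
#'   flank.
#' @return A list with `cell_id` (`NA` when unassigned), `strand`, `dist`.
#' @export
assignCellBarcode <- function(read, whitelist, design, maxEdits = 8L,
                              flankMaxEditFrac = 0.3) {
    wl <- readCellWhitelist(whitelist)
    up <- design@adapterSeqs[["cell_upstream"]]
    down <- design@adapterSeqs[["cell_downstream"]]
    constructs <- paste0(wl$barcode, down)
    upMax <- as.integer(floor(flankMaxEditFrac * nchar(up)))
    hits <- list()
    for (strand in c("+", "-")) {
        text <- if (strand == "+") read else rcomp(read)
        h <- cpp_locate(up, text, upMax)
        if (nrow(h) == 0L) next
        top <- h[which.min(h$dist), , drop = FALSE]
        wstart <- max(1L, top$end - 2L)
        wend <- min(nchar(text), top$end + 12L + nchar(down) + 8L)
        cand <- cpp_best_candidate(constructs, substr(text, wstart, wend),
                                   maxEdits)
        hits[[strand]] <- list(index = cand$index, dist = cand$dist,
                               tie = cand$tie, flankDist = top$dist,
                               strand = strand)
    }
    if (length(hits) == 0L) {
        return(list(cell_id = NA_character_, strand = NA_character_,
                    dist = NA_integer_))
    }
    passing <- Filter(function(h) h$index > 0L, hits)
    if (length(passing) == 0L) {
        return(list(cell_id = NA_character_, strand = NA_character_,
                    dist = NA_integer_))
    }
    tot <- vapply(passing, function(h) h$dist + h$flankDist, numeric(1))
    best <- which(tot == min(tot))
    cells <- vapply(passing[best], function(h) wl$cell_id[h$index],
                    character(1))
    if (length(unique(cells)) > 1L) {
        return(list(cell_id = NA_character_, strand = NA_character_,
                    dist = NA_integer_))
    }
    h <- passing[[best[1L]]]
    list(cell_id = wl$cell_id[h$index], strand = h$strand,
         dist = as.integer(h$dist))
}

#' Locate reference blocks on a read
#'
#' Approximate occurrences of every reference block (spacer blocks and the
#' pBC00 / M13F / WPRE_M13R_HSV flanks; the shared `loxP` entry, if present,
#' is skipped) on both strands, each under a per-block edit-distance
#' threshold of `maxEditFrac` of the block length. Overlapping hits are
#' resolved in favour of the lower edit distance.
#'
#' @param read a character scalar.
#' @param reference named character vector, [Biostrings::DNAStringSet], or
#'   FASTA path ([blockReference()] emits a compatible object).
#' @param maxEditFrac per-block threshold as a fraction of block length.
#' @return A data.frame (`block`, `start`, `end`, `strand`, `dist`) sorted
#'   by read position; 1-based closed coordinates.
#' @export
locateBlocks <- function(read, reference, maxEditFrac = 0.25) {
    ref <- refAsCharacter(reference)
    ref <- ref[names(ref) != "loxP"]
    pats <- c(ref, stats::setNames(rcomp(ref), names(ref)))
    strands <- rep(c("+", "-"), each = length(ref))
    maxd <- as.integer(floor(maxEditFrac * nchar(pats)))
    h <- cpp_locate_multi(pats, read, maxd)
    if (nrow(h) == 0L) {
        return(data.frame(block = character(), start = integer(),
                          end = integer(), strand = character(),
                          dist = integer(), stringsAsFactors = FALSE))
    }
    out <- data.frame(block = names(pats)[h$pattern],
                      start = h$start, end = h$end,
                      strand = strands[h$pattern],
                      dist = h$dist, stringsAsFactors = FALSE)
    ## overlap resolution: lower distance wins; >50% overlap of the shorter
    out <- out[order(out$dist, out$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
        if (!keep[i]) next
        for (j in seq_len(i - 1L)) {
            if (!keep[j]) next
            ov <- min(out$end[i], out$end[j]) -
                max(out$start[i], out$start[j]) + 1L
            if (ov <= 0L) next
            shorter <- min(out$end[i] - out$start[i],
                           out$end[j] - out$start[j]) + 1L
            if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
        }
    }
    out <- out[keep, , drop = FALSE]
    out[order(out$start), , drop = FALSE]
}

#' Assemble a Polylox barcode from block hits
#'
#' Spacer-block hits ordered by read position give the oriented-segment
#' barcode (hit strand maps to segment orientation). A read aligned in
#' reverse overall is first re-oriented using the terminal flanks. A
#' duplicate spacer id marks a chimeric observation, which is discarded.
#' The observation is full length only when both terminal flanks (pBC00 and
#' WPRE_M13R_HSV) are present and bracket the block run.
#'
#' @param hits data.frame from [locateBlocks()], sorted by position.
#' @return A list with `polylox` (canonical string or `NA`), `full_length`,
#'   and `reason` (`NA` or why the observation was discarded).
#' @export
assemblePolylox <- function(hits) {
    res <- function(polylox, full, reason = NA_character_) {
        list(polylox = polylox, full_length = full, reason = reason)
    }
    if (nrow(hits) == 0L) return(res(NA_character_, FALSE, "no_hits"))
    pb <- hits[hits$block == "pBC00", , drop = FALSE]
    wp <- hits[hits$block == "WPRE_M13R_HSV", , drop = FALSE]
    ## overall read orientation from terminal flanks
    orient <- NA_character_
    if (nrow(pb)) orient <- pb$strand[1L]
    if (nrow(wp)) {
        if (is.na(orient)) orient <- wp$strand[1L]
        else if (orient != wp$strand[1L]) {
            return(res(NA_character_, FALSE, "inconsistent_flanks"))
        }
    }
    if (identical(orient, "-")) {
        hits <- hits[rev(seq_len(nrow(hits))), , drop = FALSE]
        hits$strand <- flipOrient(hits$strand)
        pos <- max(hits$end) + 1L
        newStart <- pos - hits$end
        hits$end <- pos - hits$start
        hits$start <- newStart
        pb <- hits[hits$block == "pBC00", , drop = FALSE]
        wp <- hits[hits$block == "WPRE_M13R_HSV", , drop = FALSE]
    }
    spacers <- hits[grepl("^block[0-9]+$", hits$block), , drop = FALSE]
    ids <- as.integer(sub("^block", "", spacers$block))
    if (anyDuplicated(ids)) return(res(NA_character_, FALSE, "chimeric"))
    hasPB <- nrow(pb) > 0L
    hasWP <- nrow(wp) > 0L
    if (nrow(spacers) == 0L) {
        if (hasPB && hasWP && pb$start[1L] < wp$start[1L]) {
            return(res("EX", TRUE))
        }
        return(res(NA_character_, FALSE, "no_blocks"))
    }
    full <- hasPB && hasWP &&
        pb$start[1L] <= min(spacers$start) &&
        wp$end[1L] >= max(spacers$end)
    pol <- polyloxString(data.frame(id = ids,
                                    orientation = spacers$strand,
                                    stringsAsFactors = FALSE))
    res(pol, full)
}

#' Extract the UCI insert of a read
#'
#' Locates the 74-nt M13F and 104-nt WPRE_M13R_HSV flanks (either strand,
#' consistent orientation) and returns the intervening sequence when its
#' length is within `lenTol` of the design's UCI length.
#'
#' @param read a character scalar.
#' @param design a [CassetteDesign-class].
#' @param lenTol accepted deviation from the UCI length.
#' @param maxEditFrac flank-location threshold as a fraction of flank length.
#' @return The UCI sequence, or `NA_character_`.
#' @export
extractUci <- function(read, design, lenTol = 2L, maxEditFrac = 0.25) {
    m13f <- design@flankSeqs[["M13F"]]
    wpre <- design@flankSeqs[["WPRE_M13R_HSV"]]
    for (strand in c("+", "-")) {
        text <- if (strand == "+") read else rcomp(read)
        hm <- cpp_locate(m13f, text, as.integer(floor(maxEditFrac * nchar(m13f))))
        hw <- cpp_locate(wpre, text, as.integer(floor(maxEditFrac * nchar(wpre))))
        u <- uciBetween(text, hm, hw, design@uciLength, lenTol)
        if (!is.na(u)) return(u)
    }
    NA_character_
}

## the insert between the best M13F hit and the best downstream WPRE hit
uciBetween <- function(text, hm, hw, uciLength, lenTol) {
    if (nrow(hm) == 0L || nrow(hw) == 0L) return(NA_character_)
    m <- hm[which.min(hm$dist), , drop = FALSE]
    hw <- hw[hw$start > m$end, , drop = FALSE]
    if (nrow(hw) == 0L) return(NA_character_)
    w <- hw[which.min(hw$dist), , drop = FALSE]
    insert <- substr(text, m$end + 1L, w$start - 1L)
    if (abs(nchar(insert) - uciLength) > lenTol) return(NA_character_)
    insert
}

## Tukey-or-dominance outlier decision over sorted candidate counts
outlierPass <- function(counts, domRatio, tukeyK) {
    counts <- sort(as.numeric(counts), decreasing = TRUE)
    if (length(counts) <= 1L) return(TRUE)
    top <- counts[1L]
    rest <- counts[-1L]
    if (length(counts) >= 4L) {
        fence <- stats::quantile(rest, 0.75, names = FALSE) +
            tukeyK * stats::IQR(rest)
        top > fence
    } else {
        rest[1L] == 0 || top / rest[1L] >= domRatio
    }
}

#' Call the consensus Polylox barcode of one cell
#'
#' The most frequent barcode among the cell's observations is emitted only
#' when (1) it is supported by strictly more than `minReads` reads, (2) its
#' count is an upper outlier among the cell's candidate counts, and (3) it
#' was observed full length (see `fullLengthRule` in [callParams()]).
#'
#' @param observations data.frame with columns `polylox` and `full_length`
#'   (one row per read; `NA` barcodes are ignored).
#' @param params a [callParams()] list.
#' @return A list with `call` (string or `NA`), `nTop`, and logical `flags`
#'   (`min_reads`, `outlier`, `full_length`).
#' @export
callCellPolylox <- function(observations, params = callParams()) {
    obs <- observations[!is.na(observations$polylox), , drop = FALSE]
    if (nrow(obs) == 0L) {
        return(list(call = NA_character_, nTop = 0L,
                    flags = c(min_reads = FALSE, outlier = FALSE,
                              full_length = FALSE)))
    }
    counts <- sort(table(obs$polylox), decreasing = TRUE)
    cand <- names(counts)[1L]
    nTop <- as.integer(counts[1L])
    fullObs <- obs$full_length[obs$polylox == cand]
    passFull <- if (params$fullLengthRule == "any") {
        any(fullObs)
    } else {
        mean(fullObs) > 0.5
    }
    flags <- c(min_reads = nTop > params$minReads,
               outlier = outlierPass(counts, params$domRatio, params$tukeyK),
               full_length = passFull)
    list(call = if (all(flags)) cand else NA_character_,
         nTop = nTop, flags = flags)
}

## greedy directional collapse of error variants around abundant UCIs
clusterUcis <- function(counts, clusterDist) {
    if (clusterDist <= 0L || length(counts) <= 1L) return(counts)
    ord <- order(-as.integer(counts), names(counts))
    seqs <- names(counts)[ord]
    n <- as.integer(counts)[ord]
    reps <- character(0)
    repCount <- integer(0)
    for (k in seq_along(seqs)) {
        d <- if (length(reps)) {
            vapply(reps, cpp_edit_distance, integer(1), b = seqs[k])
        } else integer(0)
        if (length(d) && min(d) <= clusterDist) {
            hit <- which.min(d)
            repCount[hit] <- repCount[hit] + n[k]
        } else {
            reps <- c(reps, seqs[k])
            repCount <- c(repCount, n[k])
        }
    }
    stats::setNames(repCount, reps)
}

#' Call the consensus UCI of one cell
#'
#' Same three-filter structure as the Polylox call: strictly more than
#' `minReads` supporting reads, an outlier count among candidates, and -
#' when a whitelist is supplied - exact membership of the called UCI in the
#' UCI plasmid library (without a whitelist the third filter is skipped with
#' a note). Because each cell carries a single cassette, error variants
#' within `uciClusterDist` edits are collapsed onto the most abundant
#' sequence before counting.
#'
#' @param ucis character vector of per-read UCI observations (`NA` ignored).
#' @param params a [callParams()] list.
#' @param whitelist optional character vector of library UCIs.
#' @return A list with `call`, `nTop`, and logical `flags` (`min_reads`,
#'   `outlier`, `whitelist`).
#' @export
callCellUci <- function(ucis, params = callParams(), whitelist = NULL) {
    ucis <- ucis[!is.na(ucis)]
    if (length(ucis) == 0L) {
        return(list(call = NA_character_, nTop = 0L,
                    flags = c(min_reads = FALSE, outlier = FALSE,
                              whitelist = FALSE)))
    }
    counts <- clusterUcis(table(ucis), params$uciClusterDist)
    counts <- sort(counts, decreasing = TRUE)
    cand <- names(counts)[1L]
    nTop <- as.integer(counts[1L])
    passWl <- if (is.null(whitelist)) TRUE else cand %in% whitelist
    flags <- c(min_reads = nTop > params$minReads,
               outlier = outlierPass(counts, params$domRatio, params$tukeyK),
               whitelist = passWl)
    list(call = if (all(flags)) cand else NA_character_,
         nTop = nTop, flags = flags)
}

#' Call per-cell timestamp barcodes from long reads
#'
#' The full calling pipeline: every read is assigned to a whitelist cell (or
#' dropped to the unclassified pool), oriented, scanned for reference
#' blocks, assembled into a Polylox observation, and scanned for its UCI;
#' per cell, the Polylox and UCI consensus calls are made under the
#' three-filter rules, and a cell receives a timestamp barcode only when
#' both pass.
#'
#' @param reads named character vector of reads, or a FASTQ path.
#' @param design a [CassetteDesign-class].
#' @param cellWhitelist data.frame (`cell_id`, `barcode`) or TSV path.
#' @param uciWhitelist optional character vector / TSV path of library UCIs.
#' @param params a [callParams()] list.
#' @param reference optional block/flank reference overriding the design's
#'   (named character vector, DNAStringSet, or FASTA path).
#' @return A data.frame with one row per cell with at least one assigned
#'   read: `cell_id`, `polylox`, `uci`, `timestamp`, QC counts
#'   (`n_reads_cell`, `n_reads_polylox`, `n_reads_uci`,
#'   `n_reads_polylox_top`, `n_reads_uci_top`), filter flags and
#'   `fail_reasons`. The fraction of unassigned reads is attached as
#'   attribute `qc`.
#' @export
callTimestamps <- function(reads, design, cellWhitelist, uciWhitelist = NULL,
                           params = callParams(), reference = NULL) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
        reads <- readFastq(reads)
    }
    wl <- readCellWhitelist(cellWhitelist)
    if (!is.null(uciWhitelist)) uciWhitelist <- readUciWhitelist(uciWhitelist)
    ref <- refAsCharacter(if (is.null(reference)) blockReference(design)
                          else reference)
    if (length(ref) == 0L || all(nchar(ref) == 0L)) {
        stop("empty block/flank reference")
    }
    ref <- ref[names(ref) != "loxP"]

    emptyCalls <- data.frame(
        cell_id = character(), polylox = character(), uci = character(),
        timestamp = character(), n_reads_cell = integer(),
        n_reads_polylox = integer(), n_reads_uci = integer(),
        n_reads_polylox_top = integer(), n_reads_uci_top = integer(),
        pass_polylox = logical(), pass_uci = logical(),
        pass_polylox_min_reads = logical(), pass_polylox_outlier = logical(),
        pass_polylox_full_length = logical(), pass_uci_min_reads = logical(),
        pass_uci_outlier = logical(), pass_uci_whitelist = logical(),
        fail_reasons = character(), stringsAsFactors = FALSE)
    if (length(reads) == 0L) {
        attr(emptyCalls, "qc") <- list(n_reads = 0L, n_assigned = 0L,
                                       unclassified_frac = NA_real_)
        return(emptyCalls)
    }

    n <- length(reads)
    obsCell <- character(n)
    obsPol <- rep(NA_character_, n)
    obsFull <- logical(n)
    obsUci <- rep(NA_character_, n)
    for (k in seq_len(n)) {
        asg <- assignCellBarcode(reads[[k]], wl, design,
                                 maxEdits = params$maxEditsCell,
                                 flankMaxEditFrac = params$flankMaxEditFrac)
        obsCell[k] <- asg$cell_id
        if (is.na(asg$cell_id)) next
        oriented <- if (asg$strand == "-") rcomp(reads[[k]]) else reads[[k]]
        hits <- locateBlocks(oriented, ref,
                             maxEditFrac = params$blockMaxEditFrac)
        asm <- assemblePolylox(hits)
        obsPol[k] <- asm$polylox
        obsFull[k] <- isTRUE(asm$full_length)
        hm <- hits[hits$block == "M13F" & hits$strand == "+", , drop = FALSE]
        hw <- hits[hits$block == "WPRE_M13R_HSV" & hits$strand == "+", ,
                   drop = FALSE]
        obsUci[k] <- uciBetween(oriented, hm, hw, design@uciLength,
                                params$uciLenTol)
    }

    assigned <- !is.na(obsCell)
    cellsSeen <- sort(unique(obsCell[assigned]))
    rows <- lapply(cellsSeen, function(cid) {
        sel <- which(obsCell == cid & assigned)
        pcall <- callCellPolylox(
            data.frame(polylox = obsPol[sel], full_length = obsFull[sel],
                       stringsAsFactors = FALSE), params)
        ucall <- callCellUci(obsUci[sel], params, uciWhitelist)
        fails <- c(
            if (!pcall$flags[["min_reads"]]) "polylox_min_reads",
            if (!pcall$flags[["outlier"]]) "polylox_outlier",
            if (!pcall$flags[["full_length"]]) "polylox_full_length",
            if (!ucall$flags[["min_reads"]]) "uci_min_reads",
            if (!ucall$flags[["outlier"]]) "uci_outlier",
            if (!ucall$flags[["whitelist"]]) "uci_whitelist")
        passP <- !is.na(pcall$call)
        passU <- !is.na(ucall$call)
        data.frame(
            cell_id = cid,
            polylox = pcall$call, uci = ucall$call,
            timestamp = if (passP && passU) {
                paste(pcall$call, ucall$call, sep = ":")
            } else NA_character_,
            n_reads_cell = length(sel),
            n_reads_polylox = sum(!is.na(obsPol[sel])),
            n_reads_uci = sum(!is.na(obsUci[sel])),
            n_reads_polylox_top = pcall$nTop,
            n_reads_uci_top = ucall$nTop,
            pass_polylox = passP, pass_uci = passU,
            pass_polylox_min_reads = pcall$flags[["min_reads"]],
            pass_polylox_outlier = pcall$flags[["outlier"]],
            pass_polylox_full_length = pcall$flags[["full_length"]],
            pass_uci_min_reads = ucall$flags[["min_reads"]],
            pass_uci_outlier = ucall$flags[["outlier"]],
            pass_uci_whitelist = ucall$flags[["whitelist"]],
            fail_reasons = paste(fails, collapse = ";"),
            stringsAsFactors = FALSE)
    })
    calls <- if (length(rows)) do.call(rbind, rows) else emptyCalls
    rownames(calls) <- NULL
    attr(calls, "qc") <- list(
        n_reads = n,
        n_assigned = sum(assigned),
        unclassified_frac = 1 - sum(assigned) / n)
    calls
}
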