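#' Join timestamp calls with lineage labels
#'
#' Inner join on `cell_id`; cells without a confident lineage label are
#' dropped (and counted in a message), matching the rule that low-confidence
#' transcriptome assignments are excluded from linkage maps.
#'
#' @param calls filtered cell-call table (rows with non-`NA` `timestamp`).
#' @param lineages data.frame (`cell_id`, `lineage`, optional `confidence`)
#'   or TSV path.
#' @return A data.frame of annotated cells: `cell_id`, `lineage`, `polylox`,
#'   `uci`, `timestamp`.
#' @export
joinLineages <- function(calls, lineages) {
    lin <- readLineageTable(lineages)
    checkColumns(calls, c("cell_id", "polylox", "uci", "timestamp"),
                 "call table")
    if (anyDuplicated(calls$cell_id)) {
        stop("duplicate cell ids in the call table")
    }
    if (anyDuplicated(lin$cell_id)) {
        stop("duplicate cell ids in the lineage table")
    }
    lowConf <- !is.na(lin$confidence) & tolower(lin$confidence) == "low"
    if (any(lowConf)) {
        stageLog("link", sum(lowConf), " low-confidence lineage labels dropped")
        lin <- lin[!lowConf, , drop = FALSE]
    }
    called <- calls[!is.na(calls$timestamp), , drop = FALSE]
    m <- match(called$cell_id, lin$cell_id)
    dropped <- sum(is.na(m))
    if (dropped > 0L) {
        stageLog("link", dropped, " called cells lack a lineage label; dropped")
    }
    keep <- !is.na(m)
    data.frame(cell_id = called$cell_id[keep],
               lineage = lin$lineage[m[keep]],
               polylox = called$polylox[keep],
               uci = called$uci[keep],
               timestamp = called$timestamp[keep],
               stringsAsFactors = FALSE)
}

#' Cell-linkage edges from shared timestamp barcodes
#'
#' One edge per unordered pair of cells carrying an identical
#' (Polylox, UCI) timestamp barcode; a barcode shared by k cells yields
#' choose(k, 2) edges. The edge list is chord-diagram-ready.
#'
#' @param annotated output of [joinLineages()].
#' @return A data.frame (`cellA`, `cellB`, `barcode`, `lineageA`,
#'   `lineageB`).
#' @export
buildLinkageEdges <- function(annotated) {
    checkColumns(annotated, c("cell_id", "lineage", "timestamp"),
                 "annotated cell table")
    groups <- split(seq_len(nrow(annotated)), annotated$timestamp)
    out <- list()
    for (g in groups) {
        if (length(g) < 2L) next
        pr <- utils::combn(g, 2L)
        out[[length(out) + 1L]] <- data.frame(
            cellA = annotated$cell_id[pr[1L, ]],
            cellB = annotated$cell_id[pr[2L, ]],
            barcode = annotated$timestamp[pr[1L, ]],
            lineageA = annotated$lineage[pr[1L, ]],
            lineageB = annotated$lineage[pr[2L, ]],
            stringsAsFactors = FALSE)
    }
    if (length(out) == 0L) {
        return(data.frame(cellA = character(), cellB = character(),
                          barcode = character(), lineageA = character(),
                          lineageB = character(), stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$barcode, res$cellA, res$cellB), , drop = FALSE]
}

#' Lineage-by-shared-barcode count matrix
#'
#' Rows are lineages, columns the shared timestamp barcodes (observed in at
#' least two cells of any lineage), entries cell counts.
#'
#' @param annotated output of [joinLineages()].
#' @param lineages optional lineage set fixing the row order.
#' @return An integer matrix.
#' @export
lineageBarcodeMatrix <- function(annotated, lineages = NULL) {
    checkColumns(annotated, c("lineage", "timestamp"), "annotated cell table")
    if (is.null(lineages)) lineages <- sort(unique(annotated$lineage))
    counts <- table(annotated$timestamp)
    shared <- names(counts)[counts >= 2L]
    if (length(shared) == 0L) {
        warning("no shared timestamp barcodes")
        return(matrix(0L, nrow = length(lineages), ncol = 0L,
                      dimnames = list(lineages, NULL)))
    }
    sub <- annotated[annotated$timestamp %in% shared, , drop = FALSE]
    m <- table(factor(sub$lineage, levels = lineages),
               factor(sub$timestamp, levels = shared))
    mat <- matrix(as.integer(m), nrow = length(lineages),
                  dimnames = list(lineages, shared))
    mat
}

#' Pairwise lineage coupling (Spearman)
#'
#' Spearman rank correlation between every pair of lineage count vectors
#' over the shared-barcode columns. Constant vectors give an undefined
#' correlation, reported as `NA`.
#'
#' @param mat a [lineageBarcodeMatrix()] result with at least 2 columns.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
lineageCorrelation <- function(mat) {
    if (ncol(mat) < 2L) {
        stop("at least 2 shared barcodes are required for correlation")
    }
    suppressWarnings(cc <- stats::cor(t(mat), method = "spearman"))
    diag(cc) <- 1
    cc
}

## cross-lineage edge counts for integer label vectors over a fixed edge
## structure; pairCodes enumerates unordered pairs (a <= b)
pairCounts <- function(ia, ib, labels, nLin, pairCodes) {
    la <- labels[ia]
    lb <- labels[ib]
    lo <- pmin(la, lb)
    hi <- pmax(la, lb)
    tabulate(match((lo - 1L) * nLin + hi, pairCodes),
             nbins = length(pairCodes))
}

#' Observed-to-expected barcode-sharing enrichment
#'
#' For each lineage pair, compares the observed number of linkage edges
#' connecting the two lineages with its expectation under a label
#' permutation null: cell-barcode assignments stay fixed while lineage
#' labels are shuffled across cells (`nPerm` permutations). Two-sided
#' empirical p-values use the add-one correction, with
#' Benjamini-Hochberg-adjusted values alongside.
#'
#' @param annotated output of [joinLineages()].
#' @param nPerm number of permutations (>= 1).
#' @param lineages optional lineage set fixing the pair enumeration.
#' @return A data.frame (`lineageA`, `lineageB`, `observed`, `expected`,
#'   `ratio`, `p`, `q`); total edge count is invariant under permutation, so
#'   `sum(observed) == sum over permutations` of each permuted total.
#' @export
sharingEnrichment <- function(annotated, nPerm = 1000L, lineages = NULL) {
    if (nPerm < 1L) stop("nPerm must be at least 1")
    checkColumns(annotated, c("cell_id", "lineage", "timestamp"),
                 "annotated cell table")
    if (is.null(lineages)) lineages <- sort(unique(annotated$lineage))
    labels <- annotated$lineage
    ## edge structure on cell indices
    groups <- split(seq_len(nrow(annotated)), annotated$timestamp)
    ia <- integer(0)
    ib <- integer(0)
    for (g in groups) {
        if (length(g) < 2L) next
        pr <- utils::combn(g, 2L)
        ia <- c(ia, pr[1L, ])
        ib <- c(ib, pr[2L, ])
    }
    pairs <- expand.grid(a = seq_along(lineages), b = seq_along(lineages))
    pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
    nLin <- length(lineages)
    pairCodes <- (pairs$a - 1L) * nLin + pairs$b
    labInt <- match(labels, lineages)
    obs <- pairCounts(ia, ib, labInt, nLin, pairCodes)
    perm <- matrix(0L, nrow = nPerm, ncol = length(pairCodes))
    for (p in seq_len(nPerm)) {
        perm[p, ] <- pairCounts(ia, ib, sample(labInt), nLin, pairCodes)
    }
    expected <- colMeans(perm)
    pLow <- (1 + colSums(perm <= rep(obs, each = nPerm))) / (nPerm + 1)
    pHigh <- (1 + colSums(perm >= rep(obs, each = nPerm))) / (nPerm + 1)
    pval <- pmin(1, 2 * pmin(pLow, pHigh))
    data.frame(lineageA = lineages[pairs$a],
               lineageB = lineages[pairs$b],
               observed = obs,
               expected = expected,
               ratio = ifelse(expected > 0, obs / expected, NA_real_),
               p = pval,
               q = stats::p.adjust(pval, method = "BH"),
               stringsAsFactors = FALSE)
}
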