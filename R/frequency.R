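#' Per-component barcode frequencies
#'
#' Relative frequencies of each called UCI and each called Polylox barcode
#' among called cells (default) or among supporting reads, within each
#' scope. Scopes are embryoid bodies when an `eb` grouping is available,
#' pooled otherwise.
#'
#' @param calls a cell-call table (from [callTimestamps()]) containing
#'   `cell_id`, `polylox`, `uci`, and optionally `eb`.
#' @param groupBy `"eb"` to compute per-EB frequencies (requires an `eb`
#'   column or `ebMap`), `"pooled"` for a single scope.
#' @param ebMap optional data.frame (`cell_id`, `eb`) attaching cells to EBs.
#' @param mode count each called cell once (`"cells"`) or weight by
#'   supporting reads (`"reads"`, using `n_reads_polylox_top` /
#'   `n_reads_uci_top`).
#' @return A data.frame (`scope`, `component`, `barcode`, `freq`); within
#'   each (scope, component) the frequencies sum to 1.
#' @export
componentFrequencies <- function(calls, groupBy = c("pooled", "eb"),
                                 ebMap = NULL, mode = c("cells", "reads")) {
    groupBy <- match.arg(groupBy)
    mode <- match.arg(mode)
    checkColumns(calls, c("cell_id", "polylox", "uci"), "call table")
    if (nrow(calls) == 0L) stop("call table is empty")
    if (!is.null(ebMap)) {
        checkColumns(ebMap, c("cell_id", "eb"), "EB map")
        calls$eb <- ebMap$eb[match(calls$cell_id, ebMap$cell_id)]
    }
    scope <- if (groupBy == "eb") {
        if (is.null(calls$eb)) stop("groupBy='eb' requires an eb column or ebMap")
        as.character(calls$eb)
    } else {
        rep("pooled", nrow(calls))
    }
    out <- list()
    for (sc in unique(scope)) {
        sub <- calls[scope == sc, , drop = FALSE]
        for (component in c("uci", "polylox")) {
            v <- sub[[component]]
            w <- if (mode == "cells") rep(1, nrow(sub)) else {
                sub[[paste0("n_reads_", component, "_top")]]
            }
            ok <- !is.na(v)
            if (!any(ok)) {
                warning("scope ", sc, " has no called ", component,
                        "; omitted")
                next
            }
            tab <- tapply(w[ok], v[ok], sum)
            out[[length(out) + 1L]] <- data.frame(
                scope = sc, component = component,
                barcode = names(tab),
                freq = as.numeric(tab) / sum(tab),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Timestamp-barcode frequencies under independence
#'
#' Polylox recombination and UCI library draws are independent events, so
#' the frequency of a (Polylox, UCI) timestamp barcode is estimated as the
#' product of its component frequencies within the same scope.
#'
#' @param freqs output of [componentFrequencies()].
#' @param pairs data.frame (`scope`, `polylox`, `uci`) of observed pairs.
#' @return `pairs` with an added `freq` column.
#' @export
timestampFrequency <- function(freqs, pairs) {
    checkColumns(pairs, c("scope", "polylox", "uci"), "pair table")
    look <- function(component, scope, barcode) {
        i <- match(paste(scope, component, barcode),
                   paste(freqs$scope, freqs$component, freqs$barcode))
        if (anyNA(i)) {
            stop("pair references a ", component,
                 " barcode unseen in its scope")
        }
        freqs$freq[i]
    }
    pairs$freq <- look("polylox", pairs$scope, pairs$polylox) *
        look("uci", pairs$scope, pairs$uci)
    pairs
}

#' Exclude low-complexity, high-frequency timestamp barcodes
#'
#' Cells whose estimated timestamp frequency strictly exceeds `cutoff` are
#' removed (boundary values are retained). Frequencies are computed per EB
#' when grouping information is available, pooled otherwise. The empirical
#' pair frequency is emitted alongside the product estimator for
#' diagnostics.
#'
#' @param calls cell-call table; only rows with a non-`NA` `timestamp` are
#'   considered callable. A table that already carries a `freq` column
#'   (i.e. the output of a previous filter pass) is re-filtered on those
#'   frequencies, making the filter idempotent: timestamp frequencies are
#'   estimates of pre-expansion clone frequencies and are defined on the
#'   full called set, not on a filtered subset.
#' @param cutoff exclusion threshold in `(0, 1]`.
#' @param groupBy,ebMap,mode see [componentFrequencies()].
#' @return A list with `retained` (filtered call table, with `freq` and
#'   `freq_empirical` columns), `removed`, and `report` (one row:
#'   `cutoff`, `n_callable`, `n_retained`, `fraction_retained`).
#' @export
filterHighFrequency <- function(calls, cutoff = 0.005,
                                groupBy = c("pooled", "eb"), ebMap = NULL,
                                mode = c("cells", "reads")) {
    stopifnot(cutoff > 0, cutoff <= 1)
    groupBy <- match.arg(groupBy)
    mode <- match.arg(mode)
    callable <- calls[!is.na(calls$timestamp), , drop = FALSE]
    if (!is.null(ebMap) && is.null(callable$eb)) {
        checkColumns(ebMap, c("cell_id", "eb"), "EB map")
        callable$eb <- ebMap$eb[match(callable$cell_id, ebMap$cell_id)]
    }
    if (nrow(callable) == 0L) {
        report <- data.frame(cutoff = cutoff, n_callable = 0L,
                             n_retained = 0L, fraction_retained = NA_real_)
        return(list(retained = callable, removed = callable, report = report))
    }
    scope <- if (groupBy == "eb") as.character(callable$eb) else "pooled"
    if (is.null(callable$freq)) {
        freqs <- componentFrequencies(callable, groupBy = groupBy,
                                      ebMap = ebMap, mode = mode)
        pairs <- data.frame(scope = scope, polylox = callable$polylox,
                            uci = callable$uci, stringsAsFactors = FALSE)
        callable$freq <- timestampFrequency(freqs, pairs)$freq
        emp <- stats::ave(rep(1, nrow(callable)),
                          paste(scope, callable$timestamp), FUN = sum)
        callable$freq_empirical <- emp /
            stats::ave(rep(1, nrow(callable)), scope, FUN = sum)
    }
    keep <- callable$freq <= cutoff
    report <- data.frame(cutoff = cutoff,
                         n_callable = nrow(callable),
                         n_retained = sum(keep),
                         fraction_retained = mean(keep))
    list(retained = callable[keep, , drop = FALSE],
         removed = callable[!keep, , drop = FALSE],
         report = report)
}

#' Frequency-cutoff sensitivity sweep
#'
#' Applies [filterHighFrequency()] at each cutoff (defaults to the four
#' standard sensitivity cutoffs 1/1000, 3/1000, 5/1000, 1/100) and reports
#' retained counts, which are non-decreasing in the cutoff.
#'
#' @param calls cell-call table.
#' @param cutoffs numeric vector of cutoffs.
#' @param ... passed to [filterHighFrequency()].
#' @return A data.frame with one row per cutoff.
#' @export
frequencySweep <- function(calls, cutoffs = c(0.001, 0.003, 0.005, 0.01),
                           ...) {
    do.call(rbind, lapply(sort(cutoffs), function(ct) {
        filterHighFrequency(calls, cutoff = ct, ...)$report
    }))
}
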