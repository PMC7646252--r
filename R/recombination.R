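#' The intact (unrecombined) cassette state
#'
#' All segments present, forward, in id order, with loxP sites per the
#' design's orientation vector.
#'
#' @param design a [CassetteDesign-class].
#' @return A [CassetteState-class].
#' @examples
#' polyloxString(intactState(cassetteDesign(nSegments = 3)))
#' @export
intactState <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    new("CassetteState",
        siteOrientations = design@siteOrientations,
        segmentIds = seq_len(design@nSegments),
        segmentOrientations = rep("+", design@nSegments))
}

flipOrient <- function(x) ifelse(x == "+", "-", "+")

checkSitePair <- function(state, i, j) {
    k <- length(state@siteOrientations)
    if (!(i >= 1L && j <= k && i < j)) {
        stop(sprintf("site indices must satisfy 1 <= i < j <= %d", k))
    }
}

#' Apply a Cre inversion between two loxP sites
#'
#' Sites `i < j` (1-based; segment `s` lies between sites `s` and `s + 1`)
#' must have opposite orientations. Everything strictly between them is
#' reversed in order and orientation-flipped; the boundary sites stay in
#' place, so inversion is an involution.
#'
#' @param state a [CassetteState-class].
#' @param i,j site indices (1-based).
#' @return The recombined [CassetteState-class].
#' @export
applyInversion <- function(state, i, j) {
    stopifnot(is(state, "CassetteState"))
    checkSitePair(state, i, j)
    so <- state@siteOrientations
    if (so[i] == so[j]) {
        stop("not invertible: sites ", i, " and ", j,
             " have the same orientation")
    }
    segIdx <- seq(i, j - 1L)              # segments strictly between
    innerSites <- if (j - i >= 2L) seq(i + 1L, j - 1L) else integer()
    ids <- state@segmentIds
    ori <- state@segmentOrientations
    ids[segIdx] <- rev(ids[segIdx])
    ori[segIdx] <- rev(flipOrient(ori[segIdx]))
    so[innerSites] <- rev(flipOrient(so[innerSites]))
    new("CassetteState", siteOrientations = so, segmentIds = ids,
        segmentOrientations = ori)
}

#' Apply a Cre excision between two loxP sites
#'
#' Sites `i < j` must share an orientation. The intervening tokens and one of
#' the two boundary sites are deleted, leaving a single site of that
#' orientation at the junction; excision is irreversible.
#'
#' @inheritParams applyInversion
#' @return The recombined [CassetteState-class].
#' @export
applyExcision <- function(state, i, j) {
    stopifnot(is(state, "CassetteState"))
    checkSitePair(state, i, j)
    so <- state@siteOrientations
    if (so[i] != so[j]) {
        stop("not excisable: sites ", i, " and ", j,
             " have opposite orientations")
    }
    keepSeg <- setdiff(seq_along(state@segmentIds), seq(i, j - 1L))
    keepSite <- setdiff(seq_along(so), seq(i + 1L, j))
    new("CassetteState",
        siteOrientations = so[keepSite],
        segmentIds = state@segmentIds[keepSeg],
        segmentOrientations = state@segmentOrientations[keepSeg])
}

#' Legal recombination events of a state
#'
#' Every ordered site pair `(i, j)` with `i < j`: opposite orientations admit
#' an inversion, identical orientations an excision.
#'
#' @param state a [CassetteState-class].
#' @return A data.frame with columns `i`, `j`, `kind`.
#' @export
legalEvents <- function(state) {
    stopifnot(is(state, "CassetteState"))
    so <- state@siteOrientations
    k <- length(so)
    if (k < 2L) {
        return(data.frame(i = integer(), j = integer(), kind = character(),
                          stringsAsFactors = FALSE))
    }
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    i <- pairs[, "row"]
    j <- pairs[, "col"]
    kind <- ifelse(so[i] == so[j], "excision", "inversion")
    data.frame(i = i, j = j, kind = kind, stringsAsFactors = FALSE)[order(i, j), ,
                                                                    drop = FALSE]
}

#' Simulate Cre recombination of one cassette
#'
#' Draws the number of events from Poisson(`lambda`) and applies them
#' sequentially, sampling each event proportional to
#' `w(i, j, kind) = kindWeight * exp(-bias * (j - i))`, a short-range
#' preference reproducing the strong bias toward a limited set of products
#' seen in recombination data. Stops early when no legal event remains or
#' all weights vanish.
#'
#' @param state starting [CassetteState-class].
#' @param lambda Poisson mean of the event count.
#' @param bias exponential span penalty (per site of span).
#' @param excisionWeight,inversionWeight kind multipliers.
#' @param nEvents optional fixed event count overriding the Poisson draw.
#' @return The recombined [CassetteState-class].
#' @export
simulateRecombination <- function(state, lambda = 3, bias = 0.5,
                                  excisionWeight = 1, inversionWeight = 1,
                                  nEvents = NULL) {
    stopifnot(is(state, "CassetteState"), lambda >= 0)
    n <- if (is.null(nEvents)) stats::rpois(1L, lambda) else as.integer(nEvents)
    for (e in seq_len(n)) {
        ev <- legalEvents(state)
        if (nrow(ev) == 0L) break
        w <- ifelse(ev$kind == "excision", excisionWeight, inversionWeight) *
            exp(-bias * (ev$j - ev$i))
        if (all(w <= 0)) {
            warning("all event weights are zero; stopping recombination early")
            break
        }
        pick <- sample.int(nrow(ev), 1L, prob = w)
        state <- if (ev$kind[pick] == "excision") {
            applyExcision(state, ev$i[pick], ev$j[pick])
        } else {
            applyInversion(state, ev$i[pick], ev$j[pick])
        }
    }
    state
}

#' Render / parse the canonical Polylox barcode string
#'
#' Forward segment `k` renders as `"k"`, inverted as `"kR"`, joined by `"-"`;
#' the empty (fully excised) barcode renders as `"EX"`.
#'
#' @param x a [CassetteState-class], or a data.frame with columns `id` and
#'   `orientation`.
#' @return A character scalar.
#' @examples
#' parsePolylox("1-4R-9")
#' @export
polyloxString <- function(x) {
    if (is(x, "CassetteState")) x <- segmentTable(x)
    stopifnot(is.data.frame(x))
    if (nrow(x) == 0L) return("EX")
    paste0(x$id, ifelse(x$orientation == "-", "R", ""), collapse = "-")
}

#' @rdname polyloxString
#' @param string a canonical barcode string such as `"1-4R-9"` or `"EX"`.
#' @return `parsePolylox`: a data.frame with columns `id`, `orientation`.
#' @export
parsePolylox <- function(string) {
    stopifnot(is.character(string), length(string) == 1L, !is.na(string))
    if (string == "EX") {
        return(data.frame(id = integer(), orientation = character(),
                          stringsAsFactors = FALSE))
    }
    toks <- strsplit(string, "-", fixed = TRUE)[[1]]
    bad <- !grepl("^[0-9]+R?$", toks)
    if (length(toks) == 0L || any(bad)) {
        stop("malformed barcode token: ",
             if (any(bad)) paste(toks[bad], collapse = ", ") else "<empty>")
    }
    data.frame(
        id = as.integer(sub("R$", "", toks)),
        orientation = ifelse(grepl("R$", toks), "-", "+"),
        stringsAsFactors = FALSE)
}

#' Enumerate the reachable barcode space of a design
#'
#' Breadth-first closure from the intact cassette over all legal excisions
#' and inversions, deduplicated by oriented-segment sequence (loxP sites are
#' not part of barcode identity). The 9-segment alternating design reaches
#' more than 1.8 million distinct arrangements.
#'
#' @param design a [CassetteDesign-class] (or a [CassetteState-class] to
#'   enumerate from an arbitrary start).
#' @return A sorted character vector of canonical barcode strings, including
#'   the intact arrangement and, where reachable, `"EX"`.
#' @examples
#' enumerateBarcodes(cassetteDesign(nSegments = 2))
#' @export
enumerateBarcodes <- function(design) {
    so <- if (is(design, "CassetteDesign")) {
        if (design@nSegments > 9L) {
            stop("enumeration is guarded to nSegments <= 9")
        }
        design@siteOrientations
    } else if (is(design, "CassetteState")) {
        if (length(design@segmentIds) > 9L) {
            stop("enumeration is guarded to 9 segments")
        }
        if (!identical(design@segmentIds, seq_along(design@segmentIds)) ||
            any(design@segmentOrientations != "+")) {
            stop("enumeration starts from an intact state")
        }
        design@siteOrientations
    } else {
        stop("design must be a CassetteDesign or an intact CassetteState")
    }
    sort(cpp_enumerate(so))
}

#' Render a cassette state as DNA
#'
#' Concatenates, 5' to 3': the pBC00 terminal block, the loxP sites and
#' oriented spacer segments in token order (reverse-oriented tokens are
#' reverse-complemented), then M13F, the UCI (or an `N` placeholder), and
#' WPRE_M13R_HSV. Adapter/cell-barcode context is *not* included; see
#' [simulateExperiment()] for full amplicons.
#'
#' @param state a [CassetteState-class].
#' @param design the [CassetteDesign-class] providing sequences.
#' @param uci optional UCI sequence; defaults to `N` x `uciLength`.
#' @return A character scalar of DNA.
#' @export
renderSequence <- function(state, design, uci = NULL) {
    stopifnot(is(state, "CassetteState"), is(design, "CassetteDesign"))
    if (is.null(uci)) uci <- strrep("N", design@uciLength)
    ids <- state@segmentIds
    if (length(ids) && !all(ids %in% seq_len(design@nSegments))) {
        stop("state references segment ids absent from the design")
    }
    lox <- design@loxpSeq
    sites <- ifelse(state@siteOrientations == "+", lox, rcomp(lox))
    segs <- character(0)
    if (length(ids)) {
        segs <- design@segmentSeqs[paste0("block", ids)]
        rev <- state@segmentOrientations == "-"
        if (any(rev)) segs[rev] <- rcomp(segs[rev])
    }
    array <- character(2L * length(ids) + 1L)
    array[seq(1L, length(array), by = 2L)] <- sites
    if (length(ids)) array[seq(2L, length(array) - 1L, by = 2L)] <- segs
    paste0(design@flankSeqs[["pBC00"]], paste(array, collapse = ""),
           design@flankSeqs[["M13F"]], uci,
           design@flankSeqs[["WPRE_M13R_HSV"]])
}
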