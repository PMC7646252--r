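#' Design sequence accessors
#'
#' @param design a [CassetteDesign-class].
#' @return Named character vectors of the spacer, flank and adapter
#'   sequences, and the UCI length.
#' @export
segmentSequences <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    design@segmentSeqs
}

#' @rdname segmentSequences
#' @export
flankSequences <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    design@flankSeqs
}

#' @rdname segmentSequences
#' @export
adapterSequences <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    design@adapterSeqs
}

#' @rdname segmentSequences
#' @export
uciLength <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    design@uciLength
}
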