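#' @import methods
NULL

#' Canonical 34-nt loxP recognition sequence
#'
#' The Cre recognition site: two 13-nt palindromic arms around the
#' asymmetric 8-nt spacer that defines site orientation.
#' @format A length-one character vector.
#' @export
LOXP_SEQUENCE <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"

#' The five terminal lineages scored in day-14 embryoid bodies
#' @format A character vector of lineage labels.
#' @export
EB_LINEAGES <- c("EN", "S.Ect", "MES", "BP", "PGC")

#' CassetteDesign: layout of the timestamp cassette
#'
#' Describes the recombination substrate: the number and orientation of loxP
#' sites, the spacer-segment sequences between them, the flanking reference
#' blocks (pBC00 terminal block, M13F, WPRE_M13R_HSV), the UCI length, and
#' the cell-barcode/adapter context used when amplicon reads are rendered.
#'
#' @slot nSegments integer, number of spacer segments (default 9).
#' @slot siteOrientations character vector of "+"/"-" of length nSegments+1.
#' @slot segmentSeqs named character vector of spacer sequences
#'   (`block1` .. `block<n>`).
#' @slot loxpSeq the 34-nt loxP site sequence.
#' @slot flankSeqs named character vector with `pBC00`, `M13F`,
#'   `WPRE_M13R_HSV`.
#' @slot adapterSeqs named character vector with `p5`, `cell_upstream` (20 nt),
#'   `cell_downstream` (24 nt), `p3`.
#' @slot uciLength integer, UCI length (default 10).
#' @slot seed integer seed the synthetic sequences were generated from.
#' @export
setClass("CassetteDesign",
    representation(
        nSegments = "integer",
        siteOrientations = "character",
        segmentSeqs = "character",
        loxpSeq = "character",
        flankSeqs = "character",
        adapterSeqs = "character",
        uciLength = "integer",
        seed = "integer"
    )
)

setValidity("CassetteDesign", function(object) {
    msg <- character()
    n <- object@nSegments
    if (length(n) != 1L || is.na(n) || n < 1L)
        msg <- c(msg, "nSegments must be a single positive integer")
    if (length(object@siteOrientations) != n + 1L)
        msg <- c(msg, sprintf(
            "siteOrientations must have length nSegments + 1 (%d), got %d",
            n + 1L, length(object@siteOrientations)))
    if (!all(object@siteOrientations %in% c("+", "-")))
        msg <- c(msg, "siteOrientations must be '+' or '-'")
    if (length(object@segmentSeqs) != n)
        msg <- c(msg, "one segment sequence per segment is required")
    if (any(nchar(object@segmentSeqs) == 0L))
        msg <- c(msg, "segment sequences must be non-empty")
    if (nchar(object@loxpSeq) != 34L)
        msg <- c(msg, "loxP sequence must be exactly 34 nt")
    need <- c("pBC00", "M13F", "WPRE_M13R_HSV")
    if (!all(need %in% names(object@flankSeqs)))
        msg <- c(msg, "flankSeqs must contain pBC00, M13F, WPRE_M13R_HSV")
    needA <- c("p5", "cell_upstream", "cell_downstream", "p3")
    if (!all(needA %in% names(object@adapterSeqs)))
        msg <- c(msg, "adapterSeqs must contain p5, cell_upstream, cell_downstream, p3")
    else {
        if (nchar(object@adapterSeqs[["cell_upstream"]]) != 20L)
            msg <- c(msg, "cell_upstream flank must be 20 nt")
        if (nchar(object@adapterSeqs[["cell_downstream"]]) != 24L)
            msg <- c(msg, "cell_downstream flank must be 24 nt")
    }
    if (object@uciLength < 1L)
        msg <- c(msg, "uciLength must be positive")
    if (length(msg)) msg else TRUE
})

#' CassetteState: a (possibly recombined) cassette
#'
#' An ordered, alternating run of loxP sites and oriented spacer segments,
#' beginning and ending with a site. `applyInversion()` and `applyExcision()`
#' transform states; `polyloxString()` renders the oriented-segment barcode.
#'
#' @slot siteOrientations character vector of "+"/"-" (k+1 sites for k
#'   segments).
#' @slot segmentIds integer vector of segment ids (each at most once).
#' @slot segmentOrientations character vector of "+"/"-" parallel to
#'   `segmentIds`.
#' @export
setClass("CassetteState",
    representation(
        siteOrientations = "character",
        segmentIds = "integer",
        segmentOrientations = "character"
    )
)

setValidity("CassetteState", function(object) {
    msg <- character()
    k <- length(object@segmentIds)
    if (length(object@siteOrientations) != k + 1L)
        msg <- c(msg, "a cassette with k segments must carry k + 1 loxP sites")
    if (!all(object@siteOrientations %in% c("+", "-")))
        msg <- c(msg, "site orientations must be '+' or '-'")
    if (length(object@segmentOrientations) != k)
        msg <- c(msg, "one orientation per segment is required")
    if (!all(object@segmentOrientations %in% c("+", "-")))
        msg <- c(msg, "segment orientations must be '+' or '-'")
    if (anyDuplicated(object@segmentIds))
        msg <- c(msg, "segment ids must be unique within a cassette")
    if (length(msg)) msg else TRUE
})

#' SimConfig: conditions of a synthetic timestamp-barcoding experiment
#'
#' Bundles the study conditions the generator emulates: founder cells each
#' carrying one integrated cassette, a skewed UCI library, the Cre induction
#' time (day 0 of the embryoid-body time course, or day 8 after
#' postimplantation-epiblast marker expression), lineage proportions and
#' pre-induction commitment, clonal expansion, per-cell read sampling, and
#' nanopore-like read noise.
#'
#' @slot nFounders number of founder cells.
#' @slot uciLibrarySize number of distinct 10-mers in the UCI plasmid library.
#' @slot uciSkew log-normal sigma of UCI abundances (0 = uniform).
#' @slot uciUnique sample founder UCIs without replacement.
#' @slot inductionTime `"day0"` or `"day8"`.
#' @slot lineageProportions named numeric, sums to 1.
#' @slot committedLineages lineages committed before a day-8 induction.
#' @slot expansion cells per founder in the day-14 pool.
#' @slot cellsSampled cells drawn from the pool for sequencing.
#' @slot readsPerCell mean reads per cell.
#' @slot readsDispersion negative-binomial size; `Inf` fixes the count at
#'   `readsPerCell` exactly.
#' @slot subRate,insRate,delRate per-base error rates.
#' @slot truncationProb probability a read is truncated at a uniform position.
#' @slot contaminationRate probability a read's cell barcode is swapped for
#'   another sampled cell's barcode.
#' @slot ampliconMin,ampliconMax size-selection window (bp) applied to
#'   amplicons before sequencing.
#' @slot lambda mean number of Cre recombination events per cassette.
#' @slot bias exponential span-penalty of the event-weight model.
#' @slot excisionWeight,inversionWeight kind-specific event multipliers.
#' @slot nEBs number of embryoid bodies cells are assigned to.
#' @slot seed integer seed; all stage substreams derive from it.
#' @export
setClass("SimConfig",
    representation(
        nFounders = "integer",
        uciLibrarySize = "integer",
        uciSkew = "numeric",
        uciUnique = "logical",
        inductionTime = "character",
        lineageProportions = "numeric",
        committedLineages = "character",
        expansion = "integer",
        cellsSampled = "integer",
        readsPerCell = "numeric",
        readsDispersion = "numeric",
        subRate = "numeric",
        insRate = "numeric",
        delRate = "numeric",
        truncationProb = "numeric",
        contaminationRate = "numeric",
        ampliconMin = "numeric",
        ampliconMax = "numeric",
        lambda = "numeric",
        bias = "numeric",
        excisionWeight = "numeric",
        inversionWeight = "numeric",
        nEBs = "integer",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nFounders < 1L) msg <- c(msg, "nFounders must be positive")
    if (object@uciLibrarySize > 4^10)
        msg <- c(msg, "uciLibrarySize exceeds the 10-mer sequence space (4^10)")
    if (!object@inductionTime %in% c("day0", "day8"))
        msg <- c(msg, "inductionTime must be 'day0' or 'day8'")
    p <- object@lineageProportions
    if (is.null(names(p)) || any(!nzchar(names(p))))
        msg <- c(msg, "lineageProportions must be named")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        msg <- c(msg, "lineageProportions must be non-negative and sum to 1")
    if (!all(object@committedLineages %in% names(p)))
        msg <- c(msg, "committedLineages must be a subset of the lineage set")
    rates <- c(object@subRate, object@insRate, object@delRate,
               object@truncationProb, object@contaminationRate)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "error, truncation and contamination rates must lie in [0, 1]")
    if (object@cellsSampled > object@nFounders * object@expansion)
        msg <- c(msg, "cellsSampled exceeds the expanded cell pool")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (object@ampliconMin > object@ampliconMax)
        msg <- c(msg, "ampliconMin must not exceed ampliconMax")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CassetteDesign", function(object) {
    cat("CassetteDesign:", object@nSegments, "spacer segments,",
        object@nSegments + 1L, "loxP sites\n")
    cat("  site orientations:",
        paste(ifelse(object@siteOrientations == "+", ">", "<"), collapse = " "),
        "\n")
    cat("  segment lengths:",
        paste(nchar(object@segmentSeqs), collapse = ", "), "nt\n")
    cat("  flanks: pBC00", nchar(object@flankSeqs[["pBC00"]]), "nt; M13F",
        nchar(object@flankSeqs[["M13F"]]), "nt; WPRE_M13R_HSV",
        nchar(object@flankSeqs[["WPRE_M13R_HSV"]]), "nt; UCI",
        object@uciLength, "nt\n")
    cat("  intact cassette:",
        nchar(renderSequence(intactState(object), object)), "bp\n")
    invisible(object)
})

setMethod("show", "CassetteState", function(object) {
    cat("CassetteState:", length(object@segmentIds), "segments,",
        length(object@siteOrientations), "sites\n")
    cat("  barcode:", polyloxString(object), "\n")
    invisible(object)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nFounders, "founders x", object@expansion,
        "cells;", object@cellsSampled, "cells sampled;",
        "induction", object@inductionTime, "\n")
    cat("  reads/cell:", object@readsPerCell,
        if (is.finite(object@readsDispersion))
            sprintf("(NB size %g)", object@readsDispersion) else "(fixed)",
        "\n")
    cat(sprintf("  error rates sub/ins/del: %g/%g/%g; truncation %g; contamination %g\n",
        object@subRate, object@insRate, object@delRate,
        object@truncationProb, object@contaminationRate))
    cat("  lineages:",
        paste(sprintf("%s=%.2f", names(object@lineageProportions),
                      object@lineageProportions), collapse = " "), "\n")
    invisible(object)
})
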