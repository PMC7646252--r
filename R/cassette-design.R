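#' Construct a timestamp-cassette design
#'
#' Builds the recombination substrate layout: `nSegments` spacer segments
#' separated by loxP sites whose orientations default to a strictly
#' alternating pattern (five converging site pairs for the 9-segment
#' cassette), flanked by a pBC00 terminal block on the 5' side and by
#' M13F - UCI - WPRE_M13R_HSV on the 3' side. Spacer and flank sequences are
#' synthetic, drawn deterministically from `seed` and re-drawn until all
#' reference blocks are pairwise at least `minBlockDist` edits apart so block
#' mapping is unambiguous.
#'
#' @param nSegments number of spacer segments (1..9).
#' @param siteOrientations character vector of `"+"`/`"-"` of length
#'   `nSegments + 1`; default alternating starting `"+"`.
#' @param segmentLengths spacer lengths in nt, recycled to `nSegments`.
#' @param pBC00Length,p5Length,p3Length lengths of the terminal block and the
#'   PCR adapter padding.
#' @param uciLength UCI length (nt).
#' @param minBlockDist minimum pairwise edit distance between reference
#'   blocks.
#' @param seed integer seed for the synthetic sequences.
#' @return A [CassetteDesign-class] object.
#' @examples
#' design <- cassetteDesign(nSegments = 2)
#' design
#' @export
cassetteDesign <- function(nSegments = 9L,
                           siteOrientations = NULL,
                           segmentLengths = 60L,
                           pBC00Length = 300L,
                           p5Length = 30L,
                           p3Length = 30L,
                           uciLength = 10L,
                           minBlockDist = 10L,
                           seed = 20201006L) {
    nSegments <- as.integer(nSegments)
    if (is.na(nSegments) || nSegments < 1L) {
        stop("nSegments must be a positive integer")
    }
    if (is.null(siteOrientations)) {
        siteOrientations <- rep(c("+", "-"), length.out = nSegments + 1L)
    }
    if (length(siteOrientations) != nSegments + 1L) {
        stop(sprintf("siteOrientations must have length %d (nSegments + 1)",
                     nSegments + 1L))
    }
    segmentLengths <- rep(as.integer(segmentLengths),
                          length.out = nSegments)
    seqs <- withr::with_seed(stageSeed(seed, "design"), {
        drawDesignSeqs(segmentLengths, pBC00Length, p5Length, p3Length,
                       minBlockDist)
    })
    new("CassetteDesign",
        nSegments = nSegments,
        siteOrientations = as.character(siteOrientations),
        segmentSeqs = seqs$segments,
        loxpSeq = LOXP_SEQUENCE,
        flankSeqs = seqs$flanks,
        adapterSeqs = seqs$adapters,
        uciLength = as.integer(uciLength),
        seed = as.integer(seed))
}

## draw segment/flank/adapter sequences, enforcing pairwise distinctness of
## everything the caller will map against reads; each sequence is redrawn
## until it clears the required distance to all earlier ones (capped at a
## third of the shorter length, so very short spacers remain drawable)
drawDesignSeqs <- function(segmentLengths, pBC00Length, p5Length, p3Length,
                           minBlockDist) {
    n <- length(segmentLengths)
    lens <- c(segmentLengths, pBC00Length, 74L, 104L,
              p5Length, 20L, 24L, p3Length)
    nms <- c(paste0("block", seq_len(n)), "pBC00", "M13F", "WPRE_M13R_HSV",
             "p5", "cell_upstream", "cell_downstream", "p3")
    seqs <- character(length(lens))
    for (i in seq_along(lens)) {
        repeat {
            cand <- randomDNA(lens[i])
            ok <- TRUE
            for (j in seq_len(i - 1L)) {
                need <- min(minBlockDist,
                            max(1L, floor(min(lens[i], lens[j]) / 3)))
                if (cpp_edit_distance(cand, seqs[j]) < need) {
                    ok <- FALSE
                    break
                }
            }
            if (ok) break
        }
        seqs[i] <- cand
    }
    names(seqs) <- nms
    list(segments = seqs[seq_len(n)],
         flanks = seqs[n + 1:3],
         adapters = seqs[n + 4:7])
}

#' Block/flank reference sequences of a design
#'
#' The sequences mapped against long reads during barcode calling:
#' `block1..block<n>`, `pBC00`, `M13F`, `WPRE_M13R_HSV`, and `loxP`.
#'
#' @param design a [CassetteDesign-class].
#' @return A named [Biostrings::DNAStringSet].
#' @export
blockReference <- function(design) {
    stopifnot(is(design, "CassetteDesign"))
    seqs <- c(design@segmentSeqs, design@flankSeqs,
              loxP = design@loxpSeq)
    Biostrings::DNAStringSet(seqs)
}

#' Write the block/flank reference as FASTA
#'
#' @param design a [CassetteDesign-class].
#' @param path output FASTA path.
#' @return The path, invisibly.
#' @export
writeBlockReference <- function(design, path) {
    Biostrings::writeXStringSet(blockReference(design), path)
    invisible(path)
}

#' Serialise / restore a cassette design
#'
#' The JSON carries the design parameters and seed, not the sequences; the
#' constructor regenerates sequences deterministically from the seed.
#'
#' @param design a [CassetteDesign-class].
#' @param path JSON file path.
#' @return `writeDesign` the path invisibly; `readDesign` a
#'   [CassetteDesign-class].
#' @export
writeDesign <- function(design, path) {
    stopifnot(is(design, "CassetteDesign"))
    x <- list(
        n_segments = design@nSegments,
        site_orientations = design@siteOrientations,
        segment_lengths = unname(nchar(design@segmentSeqs)),
        pBC00_length = unname(nchar(design@flankSeqs[["pBC00"]])),
        p5_length = unname(nchar(design@adapterSeqs[["p5"]])),
        p3_length = unname(nchar(design@adapterSeqs[["p3"]])),
        uci_length = design@uciLength,
        seed = design@seed)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    cassetteDesign(
        nSegments = x$n_segments,
        siteOrientations = x$site_orientations,
        segmentLengths = x$segment_lengths,
        pBC00Length = x$pBC00_length,
        p5Length = x$p5_length,
        p3Length = x$p3_length,
        uciLength = x$uci_length,
        seed = x$seed)
}
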