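# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

## reverse complement for plain character vectors (ACGTN alphabet)
rcomp <- function(x) {
    cpp_revcomp(x)
}

## random DNA of given lengths under the current RNG
randomDNA <- function(lengths) {
    vapply(lengths, function(n) {
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
}

## deterministic per-stage substream seed derived from a single top-level seed
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Unit-cost edit (Levenshtein) distance
#'
#' @param a,b character scalars.
#' @return Integer edit distance.
#' @examples
#' editDistance("ACGT", "AGGT")
#' @export
editDistance <- function(a, b) {
    stopifnot(is.character(a), is.character(b),
              length(a) == 1L, length(b) == 1L)
    cpp_edit_distance(a, b)
}

## message to stderr with a stage tag
stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

## stop unless all columns present
checkColumns <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
        stop(sprintf("%s is missing required column(s): %s", what,
                     paste(miss, collapse = ", ")), call. = FALSE)
    }
    invisible(df)
}
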