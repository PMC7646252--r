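#' Read / write FASTQ and FASTA
#'
#' Thin wrappers around Biostrings. `writeFastq` emits uniform placeholder
#' qualities (`I`), as base qualities carry no information in this pipeline.
#'
#' @param seqs named character vector of DNA sequences.
#' @param path file path.
#' @return `readFastq`/`readFasta`: a named character vector; writers return
#'   the path invisibly.
#' @export
writeFastq <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
        strrep("I", n)
    }, character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
    invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    stats::setNames(as.character(x), names(x))
}

#' @rdname writeFastq
#' @export
readFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    stats::setNames(as.character(x), names(x))
}

## TSV conventions: header row, tab-delimited, UTF-8, no quoting
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

readTsv <- function(path, required = NULL, what = path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            fileEncoding = "UTF-8")
    if (!is.null(required)) checkColumns(df, required, what)
    df
}

#' Read a cell-barcode whitelist
#'
#' TSV with columns `cell_id` and `barcode` (12 nt). Duplicate barcodes are a
#' configuration error.
#'
#' @param path TSV path, or a data.frame already in memory.
#' @return A data.frame with columns `cell_id`, `barcode`.
#' @export
readCellWhitelist <- function(path) {
    df <- if (is.data.frame(path)) path else {
        readTsv(path, c("cell_id", "barcode"), "cell whitelist")
    }
    checkColumns(df, c("cell_id", "barcode"), "cell whitelist")
    if (any(nchar(df$barcode) != 12L)) {
        stop("cell barcodes must be exactly 12 nt")
    }
    if (anyDuplicated(df$barcode)) {
        stop("duplicate barcodes in the cell whitelist")
    }
    if (anyDuplicated(df$cell_id)) {
        stop("duplicate cell ids in the cell whitelist")
    }
    df
}

#' Read a UCI whitelist
#'
#' @param path TSV path with column `uci`, or a character vector of UCI
#'   sequences, or a data.frame with a `uci` column.
#' @return A character vector of UCI sequences.
#' @export
readUciWhitelist <- function(path) {
    if (is.data.frame(path)) return(path$uci)
    stopifnot(is.character(path))
    if (length(path) > 1L || grepl("^[ACGTN]+$", path)) return(path)
    readTsv(path, "uci", "UCI whitelist")$uci
}

#' Read a per-cell lineage table
#'
#' TSV with columns `cell_id`, `lineage` and optionally `confidence`
#' (`"high"`/`"low"`; low-confidence rows are dropped by [joinLineages()]).
#'
#' @param path TSV path or data.frame.
#' @return A data.frame.
#' @export
readLineageTable <- function(path) {
    df <- if (is.data.frame(path)) path else {
        readTsv(path, c("cell_id", "lineage"), "lineage table")
    }
    checkColumns(df, c("cell_id", "lineage"), "lineage table")
    if (is.null(df$confidence)) df$confidence <- "high"
    df
}
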