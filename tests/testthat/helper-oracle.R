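# Independent oracles used across the suite. Deliberately implemented on a
# different representation (flat token vectors) than the package internals.

# token encoding: sites "L+"/"L-", segment k forward "k+", inverted "k-"

oracleTokens <- function(siteOri) {
    n <- length(siteOri) - 1L
    toks <- character(0)
    for (k in seq_len(n)) {
        toks <- c(toks, paste0("L", siteOri[k]), paste0(k, "+"))
    }
    c(toks, paste0("L", siteOri[n + 1L]))
}

oracleFlip <- function(tok) {
    ori <- substring(tok, nchar(tok))
    paste0(substr(tok, 1L, nchar(tok) - 1L), if (ori == "+") "-" else "+")
}

oracleSitePos <- function(toks) which(substr(toks, 1L, 1L) == "L")

oracleSiteOri <- function(tok) substring(tok, nchar(tok))

# apply the event defined by site token positions a < b
oracleEvent <- function(toks, a, b) {
    if (oracleSiteOri(toks[a]) != oracleSiteOri(toks[b])) {
        mid <- if (b - a > 1L) {
            rev(vapply(toks[(a + 1L):(b - 1L)], oracleFlip, character(1)))
        } else character(0)
        c(toks[seq_len(a)], mid, toks[b:length(toks)])
    } else {
        rest <- if (b < length(toks)) {
            toks[(b + 1L):length(toks)]
        } else character(0)
        c(toks[seq_len(a)], rest)
    }
}

oracleCode <- function(toks) {
    segs <- toks[substr(toks, 1L, 1L) != "L"]
    if (length(segs) == 0L) return("EX")
    paste(vapply(segs, function(t) {
        id <- substr(t, 1L, nchar(t) - 1L)
        if (oracleSiteOri(t) == "-") paste0(id, "R") else id
    }, character(1)), collapse = "-")
}

# exhaustive BFS closure over all legal events
oracleEnumerate <- function(siteOri) {
    start <- oracleTokens(siteOri)
    seen <- new.env(hash = TRUE)
    codes <- new.env(hash = TRUE)
    queue <- list(start)
    assign(paste(start, collapse = " "), TRUE, envir = seen)
    assign(oracleCode(start), TRUE, envir = codes)
    while (length(queue)) {
        s <- queue[[1L]]
        queue <- queue[-1L]
        sp <- oracleSitePos(s)
        for (ai in seq_along(sp)) {
            for (bi in seq_along(sp)) {
                if (bi <= ai) next
                t <- oracleEvent(s, sp[ai], sp[bi])
                key <- paste(t, collapse = " ")
                if (!exists(key, envir = seen, inherits = FALSE)) {
                    assign(key, TRUE, envir = seen)
                    assign(oracleCode(t), TRUE, envir = codes)
                    queue <- c(queue, list(t))
                }
            }
        }
    }
    sort(ls(codes))
}

# best semi-global (pattern-infix) edit distance via base adist over all
# substrings -- quadratic, for tiny cases only
oracleInfixDist <- function(pattern, text) {
    n <- nchar(text)
    best <- nchar(pattern)
    for (i in seq_len(n)) {
        for (j in i:n) {
            best <- min(best,
                        utils::adist(pattern, substr(text, i, j))[1, 1])
        }
    }
    best
}

randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
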