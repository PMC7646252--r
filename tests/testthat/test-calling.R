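# Per-read extraction and per-cell consensus calling.

mkDesign <- function() cassetteDesign(nSegments = 3, seed = 5L)

# an error-free amplicon read for a given barcode/uci/cell-barcode
mkRead <- function(design, polylox, uci, cellBarcode,
                   sites = NULL) {
    ad <- adapterSequences(design)
    seg <- parsePolylox(polylox)
    if (is.null(sites)) {
        sites <- rep(c("+", "-"), length.out = nrow(seg) + 1L)
    }
    st <- new("CassetteState", siteOrientations = sites,
              segmentIds = as.integer(seg$id),
              segmentOrientations = seg$orientation)
    paste0(ad[["p5"]], ad[["cell_upstream"]], cellBarcode,
           ad[["cell_downstream"]], renderSequence(st, design, uci),
           ad[["p3"]])
}

test_that("cell-barcode assignment picks the unique best whitelist hit", {
    d <- mkDesign()
    set.seed(21)
    wl <- data.frame(cell_id = c("c1", "c2", "c3"),
                     barcode = makeCellBarcodes(3),
                     stringsAsFactors = FALSE)
    read <- mkRead(d, "1-2-3", "ACGTACGTAC", wl$barcode[2])
    expect_identical(assignCellBarcode(read, wl, d)$cell_id, "c2")
    # reverse-strand reads assign identically
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    asg <- assignCellBarcode(rc, wl, d)
    expect_identical(asg$cell_id, "c2")
    expect_identical(asg$strand, "-")

    # one substitution in the barcode: still the unique best
    sub <- read
    pos <- nchar(adapterSequences(d)[["p5"]]) + 20L + 5L
    substr(sub, pos, pos) <- if (substr(sub, pos, pos) == "A") "C" else "A"
    # brute-force oracle: construct distance per whitelist entry
    down <- adapterSequences(d)[["cell_downstream"]]
    oracle <- vapply(wl$barcode, function(b) {
        oracleInfixDist(paste0(b, down),
                        substr(sub, pos - 10L, pos + 45L))
    }, numeric(1))
    expect_identical(assignCellBarcode(sub, wl, d, maxEdits = 3)$cell_id,
                     wl$cell_id[which.min(oracle)])

    # equal best score across two entries: no assignment
    wlTie <- data.frame(cell_id = c("a", "b"),
                        barcode = c("AAAAAAAAAAAA", "AAAAAAAAAAAT"),
                        stringsAsFactors = FALSE)
    readTie <- mkRead(d, "1", "ACGTACGTAC", "AAAAAAAAAAAC",
                      sites = c("+", "-"))
    expect_true(is.na(assignCellBarcode(readTie, wlTie, d)$cell_id))

    expect_error(
        assignCellBarcode(read, data.frame(cell_id = c("x", "y"),
                                           barcode = rep("ACGTACGTACGT", 2)),
                          d),
        "duplicate")
})

test_that("block location finds planted blocks in order and ignores noise", {
    d <- mkDesign()
    ref <- blockReference(d)
    read <- mkRead(d, "1-3R", "ACGTACGTAC", "ACGTACGTACGT",
                   sites = c("+", "-", "+"))
    h <- locateBlocks(read, ref)
    spacers <- h[grepl("^block", h$block), ]
    expect_identical(spacers$block, c("block1", "block3"))
    expect_identical(spacers$strand, c("+", "-"))
    expect_true(all(c("pBC00", "WPRE_M13R_HSV", "M13F") %in% h$block))
    expect_true(!is.unsorted(h$start))

    # a shuffled sequence of the same composition yields no hits
    set.seed(31)
    shuffled <- paste(sample(strsplit(read, "")[[1]]), collapse = "")
    expect_identical(nrow(locateBlocks(shuffled, ref)), 0L)
})

test_that("assembly maps hits to barcodes, flags, chimeras and reversals", {
    hit <- function(block, start, end, strand) {
        data.frame(block = block, start = start, end = end, strand = strand,
                   dist = 0L, stringsAsFactors = FALSE)
    }
    full <- rbind(hit("pBC00", 1, 300, "+"),
                  hit("block1", 335, 394, "+"),
                  hit("block4", 429, 488, "-"),
                  hit("block9", 523, 582, "+"),
                  hit("M13F", 617, 690, "+"),
                  hit("WPRE_M13R_HSV", 701, 804, "+"))
    a <- assemblePolylox(full)
    expect_identical(a$polylox, "1-4R-9")
    expect_true(a$full_length)

    noPB <- full[full$block != "pBC00", ]
    b <- assemblePolylox(noPB)
    expect_identical(b$polylox, "1-4R-9")
    expect_false(b$full_length)

    dup <- rbind(full, hit("block4", 900, 959, "+"))
    expect_true(is.na(assemblePolylox(dup)$polylox))
    expect_identical(assemblePolylox(dup)$reason, "chimeric")

    # reversed read: same barcode after flank-based re-orientation
    revhits <- full
    revhits$strand <- rev(ifelse(full$strand == "+", "-", "+"))
    revhits$block <- rev(full$block)
    r <- assemblePolylox(revhits)
    expect_identical(r$polylox, "1-4R-9")
    expect_true(r$full_length)

    # empty barcode: terminal flanks only
    ex <- rbind(hit("pBC00", 1, 300, "+"),
                hit("M13F", 340, 413, "+"),
                hit("WPRE_M13R_HSV", 424, 527, "+"))
    e <- assemblePolylox(ex)
    expect_identical(e$polylox, "EX")
    expect_true(e$full_length)
})

test_that("UCI extraction needs both flanks, consistent strand, sane length", {
    d <- mkDesign()
    fl <- flankSequences(d)
    exact <- paste0(fl[["M13F"]], "ACGTACGTAC", fl[["WPRE_M13R_HSV"]])
    expect_identical(extractUci(exact, d), "ACGTACGTAC")
    # reverse strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exact)))
    expect_identical(extractUci(rc, d), "ACGTACGTAC")
    # missing M13F
    expect_true(is.na(extractUci(paste0("ACGTACGTAC",
                                        fl[["WPRE_M13R_HSV"]]), d)))
    # a 14-nt insert exceeds the +/-2 tolerance
    long <- paste0(fl[["M13F"]], "ACGTACGTACACGT", fl[["WPRE_M13R_HSV"]])
    expect_true(is.na(extractUci(long, d)))
    expect_identical(extractUci(long, d, lenTol = 5L), "ACGTACGTACACGT")
})

test_that("polylox consensus enforces the three filters", {
    obs <- function(...) {
        x <- c(...)
        data.frame(polylox = x, full_length = rep(TRUE, length(x)),
                   stringsAsFactors = FALSE)
    }
    p <- callParams()
    # 40 vs 2: accepted
    a <- callCellPolylox(obs(rep("1-4R-9", 40), rep("1-9", 2)), p)
    expect_identical(a$call, "1-4R-9")
    expect_true(all(a$flags))
    # 25 reads of one barcode: fails the >30 rule
    b <- callCellPolylox(obs(rep("1-2", 25)), p)
    expect_true(is.na(b$call))
    expect_false(b$flags[["min_reads"]])
    expect_true(b$flags[["outlier"]])
    # 31 reads: the boundary passes
    expect_identical(callCellPolylox(obs(rep("1-2", 31)), p)$call, "1-2")
    # 35 vs 34: dominance fallback rejects
    c_ <- callCellPolylox(obs(rep("A", 35), rep("B", 34)), p)
    expect_true(is.na(c_$call))
    expect_false(c_$flags[["outlier"]])
    # full-length rule: candidate never seen full length
    d_ <- callCellPolylox(data.frame(polylox = rep("1-2", 40),
                                     full_length = FALSE), p)
    expect_true(is.na(d_$call))
    expect_false(d_$flags[["full_length"]])
    # one full-length observation suffices under the default rule
    e_ <- callCellPolylox(data.frame(polylox = rep("1-2", 40),
                                     full_length = c(TRUE, rep(FALSE, 39))),
                          p)
    expect_identical(e_$call, "1-2")
})

test_that("UCI consensus collapses error variants and applies the whitelist", {
    p <- callParams()
    wl <- c("TTGGCCAATT", "ACGTACGTAC")
    # all filters pass
    a <- callCellUci(rep("TTGGCCAATT", 50), p, wl)
    expect_identical(a$call, "TTGGCCAATT")
    # non-whitelisted candidate is rejected when a whitelist is given
    b <- callCellUci(rep("GGGGGTTTTT", 50), p, wl)
    expect_true(is.na(b$call))
    expect_false(b$flags[["whitelist"]])
    # ... but called without one
    expect_identical(callCellUci(rep("GGGGGTTTTT", 50), p)$call, "GGGGGTTTTT")
    # 31 vs 1 distant second: passes the boundary and dominance
    c_ <- callCellUci(c(rep("TTGGCCAATT", 31), "CCCCCAAAAA"), p, wl)
    expect_identical(c_$call, "TTGGCCAATT")
    # error variants within the cluster radius support the modal sequence
    d_ <- callCellUci(c(rep("TTGGCCAATT", 25), rep("TTGGACAATT", 5),
                        rep("TTGGCCATT", 3)), p, wl)
    expect_identical(d_$call, "TTGGCCAATT")
    expect_identical(d_$nTop, 33L)
    # with clustering disabled the same input fails the read floor
    p0 <- callParams(uciClusterDist = 0L)
    expect_true(is.na(callCellUci(c(rep("TTGGCCAATT", 25),
                                    rep("TTGGACAATT", 5),
                                    rep("TTGGCCATT", 3)), p0, wl)$call))
})

test_that("end-to-end calling recovers a zero-noise simulation exactly", {
    d <- mkDesign()
    cfg <- cleanConfig(nFounders = 5L, cellsSampled = 10L, expansion = 4L,
                       readsPerCell = 40, seed = 61L)
    sim <- simulateExperiment(cfg, d)
    calls <- callTimestamps(sim$reads, d, sim$cellWhitelist,
                            uciWhitelist = sim$uciLibrary$uci)
    tt <- truthTable(sim)
    m <- match(calls$cell_id, tt$cell_id)
    expect_identical(nrow(calls), 10L)
    expect_true(all(!is.na(calls$timestamp)))
    expect_identical(calls$polylox, tt$polylox[m])
    expect_identical(calls$uci, tt$uci[m])
    # every call lies in the enumerated reachable space
    expect_true(all(calls$polylox %in% enumerateBarcodes(d)))
    # calling is invariant to read order
    set.seed(2)
    shuffled <- sim$reads[sample(length(sim$reads))]
    calls2 <- callTimestamps(shuffled, d, sim$cellWhitelist,
                             uciWhitelist = sim$uciLibrary$uci)
    expect_identical(calls, calls2, ignore_attr = TRUE)
})

test_that("raising the read floor never increases the number of called cells", {
    d <- mkDesign()
    sim <- simulateExperiment(cleanConfig(nFounders = 4L, cellsSampled = 8L,
                                          expansion = 2L, readsPerCell = 35,
                                          seed = 62L), d)
    nCalled <- vapply(c(10L, 30L, 34L, 60L), function(mr) {
        calls <- callTimestamps(sim$reads, d, sim$cellWhitelist,
                                params = callParams(minReads = mr))
        sum(!is.na(calls$timestamp))
    }, integer(1))
    expect_true(all(diff(nCalled) <= 0L))
    expect_identical(nCalled[4], 0L)
})

test_that("a cell failing one component keeps its row but gets no timestamp", {
    d <- mkDesign()
    sim <- simulateExperiment(cleanConfig(nFounders = 3L, cellsSampled = 6L,
                                          expansion = 2L, readsPerCell = 40,
                                          seed = 63L), d)
    # a whitelist that contains none of the true UCIs fails filter 3
    calls <- callTimestamps(sim$reads, d, sim$cellWhitelist,
                            uciWhitelist = c("AAAAAAAAAA"))
    expect_true(all(calls$pass_polylox))
    expect_true(all(!calls$pass_uci))
    expect_true(all(is.na(calls$timestamp)))
    expect_true(all(grepl("uci_whitelist", calls$fail_reasons)))
})

test_that("empty input produces an empty, well-formed call table", {
    d <- mkDesign()
    wl <- data.frame(cell_id = "c1", barcode = "ACGTACGTACGT",
                     stringsAsFactors = FALSE)
    calls <- callTimestamps(character(0), d, wl)
    expect_identical(nrow(calls), 0L)
    expect_true(all(c("cell_id", "polylox", "uci", "timestamp",
                      "fail_reasons") %in% names(calls)))
})
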