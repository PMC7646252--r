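test_that("intact states have the designed structure and render identically", {
    d9 <- cassetteDesign()
    s9 <- intactState(d9)
    expect_identical(nSegments(s9), 9L)
    expect_length(siteOrientations(s9), 10L)
    expect_identical(polyloxString(s9), "1-2-3-4-5-6-7-8-9")

    d1 <- tinyDesign(1L, siteOrientations = c("+", "-"))
    s1 <- intactState(d1)
    expect_identical(siteOrientations(s1), c("+", "-"))
    expect_identical(segmentTable(s1),
                     data.frame(id = 1L, orientation = "+",
                                stringsAsFactors = FALSE))

    expect_identical(polyloxString(intactState(tinyDesign(2L))), "1-2")
})

test_that("inversion flips and reverses the enclosed tokens and is an involution", {
    s2 <- intactState(tinyDesign(2L))        # sites + - +
    inv <- applyInversion(s2, 1L, 2L)
    expect_identical(polyloxString(inv), "1R-2")
    expect_identical(polyloxString(applyInversion(inv, 1L, 2L)), "1-2")

    # 3 segments, sites + - + -, full-span inversion: hand-worked reversal
    s3 <- intactState(tinyDesign(3L))
    inv3 <- applyInversion(s3, 1L, 4L)
    expect_identical(polyloxString(inv3), "3R-2R-1R")
    expect_identical(siteOrientations(inv3), c("+", "-", "+", "-"))
    expect_identical(polyloxString(applyInversion(inv3, 1L, 4L)), "1-2-3")

    expect_error(applyInversion(s3, 1L, 3L), "not invertible")
})

test_that("excision removes the interval plus one site, irreversibly", {
    s2 <- intactState(tinyDesign(2L))        # sites + - +
    ex <- applyExcision(s2, 1L, 3L)
    expect_identical(polyloxString(ex), "EX")
    expect_identical(siteOrientations(ex), "+")

    s3 <- intactState(cassetteDesign(nSegments = 3,
                                     siteOrientations = c("+", "-", "+", "-")))
    ex2 <- applyExcision(s3, 2L, 4L)         # sites 2 and 4 both '-'
    expect_identical(polyloxString(ex2), "1")
    expect_identical(siteOrientations(ex2), c("+", "-"))
    expect_lt(length(ex2@segmentIds), length(s3@segmentIds))

    expect_error(applyExcision(s2, 1L, 2L), "not excisable")
})

test_that("barcode strings round-trip and malformed strings fail loudly", {
    expect_identical(polyloxString(parsePolylox("1-4R-9")), "1-4R-9")
    expect_identical(polyloxString(parsePolylox("EX")), "EX")
    expect_identical(parsePolylox("3R"),
                     data.frame(id = 3L, orientation = "-",
                                stringsAsFactors = FALSE))
    expect_error(parsePolylox("1-xy-3"), "malformed")
    # round trip through a recombined state
    st <- applyInversion(intactState(tinyDesign(3L)), 1L, 4L)
    expect_identical(parsePolylox(polyloxString(st))$id, st@segmentIds)
})

test_that("enumeration matches an exhaustive token-level BFS oracle", {
    # n=1 opposite sites: inversion only
    expect_identical(enumerateBarcodes(tinyDesign(1L, siteOrientations = c("+", "-"))),
                     c("1", "1R"))
    # n=1 same-orientation sites: only excision is legal
    expect_identical(enumerateBarcodes(tinyDesign(1L, siteOrientations = c("+", "+"))),
                     c("1", "EX"))
    # n=2 alternating: the five known products
    expect_identical(enumerateBarcodes(tinyDesign(2L)),
                     c("1-2", "1-2R", "1R-2", "1R-2R", "EX"))
    # full agreement with the oracle on n <= 3, assorted orientation vectors
    for (so in list(c("+", "-"), c("+", "+"), c("+", "-", "+"),
                    c("+", "+", "-"), c("+", "-", "+", "-"),
                    c("+", "+", "+", "-"))) {
        d <- cassetteDesign(nSegments = length(so) - 1L,
                            siteOrientations = so)
        expect_identical(enumerateBarcodes(d), oracleEnumerate(so),
                         info = paste(so, collapse = ""))
    }
})

test_that("reachable states keep segment subsets in original relative order up to inversion", {
    # BFS-oracle-backed structural property on the n=3 alternating design
    codes <- enumerateBarcodes(tinyDesign(3L))
    for (code in codes) {
        seg <- parsePolylox(code)
        expect_true(all(seg$id %in% 1:3))
        expect_identical(anyDuplicated(seg$id), 0L)
    }
    # enumeration is order-independent: reversing the orientation vector
    # relabels but preserves the count
    a <- enumerateBarcodes(cassetteDesign(nSegments = 3,
                                          siteOrientations = c("+", "-", "+", "-")))
    b <- enumerateBarcodes(cassetteDesign(nSegments = 3,
                                          siteOrientations = c("-", "+", "-", "+")))
    expect_identical(length(a), length(b))
})

test_that("simulated recombination is seeded, closed, and stops at lambda = 0", {
    d2 <- tinyDesign(2L)
    s2 <- intactState(d2)
    expect_identical(polyloxString(simulateRecombination(s2, lambda = 0)),
                     "1-2")
    set.seed(42)
    a <- polyloxString(simulateRecombination(s2, lambda = 3))
    set.seed(42)
    b <- polyloxString(simulateRecombination(s2, lambda = 3))
    expect_identical(a, b)

    reachable <- enumerateBarcodes(d2)
    set.seed(7)
    draws <- replicate(2000, polyloxString(simulateRecombination(s2, lambda = 3)))
    expect_true(all(draws %in% reachable))
    # bias toward short-range events: both event kinds appear
    expect_gt(length(unique(draws)), 2L)
})

test_that("rendered sequences have the expected arithmetic and strand symmetry", {
    d <- cassetteDesign(nSegments = 9, segmentLengths = 20L)
    flank <- flankSequences(d)
    fixed <- sum(nchar(flank)) + uciLength(d)
    intactLen <- nchar(renderSequence(intactState(d), d))
    expect_identical(intactLen - fixed, 9L * 20L + 10L * 34L)  # 520-nt array

    # empty barcode: a single surviving site
    d2 <- tinyDesign(2L)
    ex <- applyExcision(intactState(d2), 1L, 3L)
    fixed2 <- sum(nchar(flankSequences(d2))) + uciLength(d2)
    expect_identical(nchar(renderSequence(ex, d2)) - fixed2, 34L)

    # reverse-complement symmetry of a single-segment array under a
    # (+,-) site pair
    dd <- cassetteDesign(nSegments = 1, siteOrientations = c("+", "-"))
    fwd <- new("CassetteState", siteOrientations = c("+", "-"),
               segmentIds = 1L, segmentOrientations = "+")
    rev <- new("CassetteState", siteOrientations = c("+", "-"),
               segmentIds = 1L, segmentOrientations = "-")
    arrayOf <- function(st) {
        r <- renderSequence(st, dd)
        pb <- nchar(flankSequences(dd)[["pBC00"]])
        substr(r, pb + 1L, nchar(r) - 74L - 10L - 104L)
    }
    expect_identical(arrayOf(rev),
                     as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(arrayOf(fwd)))))

    # missing segment sequence errors
    bad <- new("CassetteState", siteOrientations = c("+", "-", "+"),
               segmentIds = c(1L, 7L), segmentOrientations = c("+", "+"))
    expect_error(renderSequence(bad, d2), "absent from the design")
})

test_that("design serialisation regenerates identical sequences from the seed", {
    d <- cassetteDesign(nSegments = 3, seed = 77L)
    path <- withr::local_tempfile(fileext = ".json")
    writeDesign(d, path)
    d2 <- readDesign(path)
    expect_identical(segmentSequences(d), segmentSequences(d2))
    expect_identical(flankSequences(d), flankSequences(d2))
    expect_identical(siteOrientations(d), siteOrientations(d2))
})
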