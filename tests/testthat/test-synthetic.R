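test_that("UCI libraries are distinct, normalised, seeded, and bounded", {
    set.seed(1)
    lib <- drawUciLibrary(5000, skew = 0.5)
    expect_identical(nrow(lib), 5000L)
    expect_identical(anyDuplicated(lib$uci), 0L)
    expect_true(all(nchar(lib$uci) == 10L))
    expect_equal(sum(lib$weight), 1)

    set.seed(9)
    flat <- drawUciLibrary(200, skew = 0)
    expect_lt(max(flat$weight) / min(flat$weight), 1 + 1e-9)

    set.seed(3); a <- drawUciLibrary(50, 0.5)
    set.seed(3); b <- drawUciLibrary(50, 0.5)
    expect_identical(a, b)

    expect_error(drawUciLibrary(4^10 + 1), "exceeds")
    expect_error(drawUciLibrary(5, length = 1L), "exceeds")
})

test_that("read mutation honours its limits and its error budget", {
    s <- randomSeq(300)
    expect_identical(mutateReads(s, 0, 0, 0, 0)$seq, s)
    expect_identical(mutateReads(s, 0, 0, 1, 0)$seq, "")

    # 10 kb at rates .02/.03/.04: edit distance within 3 sigma of the
    # binomial op-count expectation
    set.seed(5)
    long <- randomSeq(10000)
    mut <- mutateReads(long, 0.02, 0.03, 0.04, 0)$seq
    expected <- 10000 * 0.09
    sigma <- sqrt(10000 * 0.09 * 0.91)
    d <- editDistance(long, mut)
    expect_gt(d, expected - 3 * sigma)
    expect_lt(d, expected + 3 * sigma)

    # truncation keeps a prefix and records the cut
    set.seed(6)
    tr <- mutateReads(s, 0, 0, 0, 1)
    expect_false(is.na(tr$truncatedAt))
    expect_identical(nchar(tr$seq), tr$truncatedAt)
    expect_identical(tr$seq, substr(s, 1, tr$truncatedAt))
})

test_that("contamination reassigns the stated fraction of reads", {
    cells <- 1:10
    origin <- rep(cells, each = 100)
    expect_identical(contaminateAssignments(origin, cells, 0), origin)

    set.seed(2)
    two <- contaminateAssignments(c(1L, 1L, 2L), 1:2, 1)
    expect_identical(two, c(2L, 2L, 1L))

    set.seed(8)
    big <- contaminateAssignments(rep(1:50, each = 200), 1:50, 0.05)
    frac <- mean(big != rep(1:50, each = 200))
    ci <- qbinom(c(0.005, 0.995), 10000, 0.05) / 10000
    expect_gt(frac, ci[1])
    expect_lt(frac, ci[2])
})

test_that("simulated truth has the configured cell counts and founder links", {
    cfg <- cleanConfig(nFounders = 2L, expansion = 3L, cellsSampled = 6L,
                       readsPerCell = 5)
    sim <- simulateExperiment(cfg, tinyDesign(2L))
    expect_identical(nrow(sim$truth$cells), 6L)
    expect_true(all(sim$truth$cells$founder_id %in%
                    sim$truth$founders$founder_id))
    expect_identical(anyDuplicated(sim$truth$cells$barcode), 0L)
    expect_true(all(sim$truth$reads$cell_id %in% sim$truth$cells$cell_id))
})

test_that("zero-noise reads carry every truth component verbatim and in order", {
    d <- tinyDesign(2L)
    sim <- simulateExperiment(cleanConfig(readsPerCell = 3, seed = 41L), d)
    tt <- truthTable(sim)
    segs <- segmentSequences(d)
    flanks <- flankSequences(d)
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    rt <- sim$truth$reads
    set.seed(1)
    for (k in sample(seq_along(sim$reads), 12)) {
        cell <- rt$cell_id[match(names(sim$reads)[k], rt$read_id)]
        row <- tt[tt$cell_id == cell, ]
        seg <- parsePolylox(row$polylox)
        expected <- c(flanks[["pBC00"]],
                      if (nrow(seg)) ifelse(seg$orientation == "+",
                                            segs[seg$id],
                                            vapply(segs[seg$id], rc,
                                                   character(1))),
                      flanks[["M13F"]], row$uci, flanks[["WPRE_M13R_HSV"]])
        hit <- FALSE
        for (r in c(sim$reads[[k]], rc(sim$reads[[k]]))) {
            pos <- vapply(expected, function(s) {
                regexpr(s, r, fixed = TRUE)[1]
            }, numeric(1))
            if (all(pos > 0) && !is.unsorted(pos)) hit <- TRUE
        }
        expect_true(hit)
    }
})

test_that("day-8 committed founders give disjoint barcode sets; day-0 shares", {
    cfg8 <- cleanConfig(nFounders = 40L, expansion = 6L, cellsSampled = 120L,
                        readsPerCell = 1, seed = 55L,
                        inductionTime = "day8", uciUnique = TRUE)
    sim8 <- simulateExperiment(cfg8, tinyDesign(2L), reads = FALSE)
    tt <- truthTable(sim8)
    pgc <- paste(tt$polylox, tt$uci)[tt$lineage == "PGC"]
    soma <- paste(tt$polylox, tt$uci)[tt$lineage != "PGC"]
    expect_length(intersect(pgc, soma), 0L)
    # committed founders produce only their committed lineage
    com <- sim8$truth$founders
    com <- com[!is.na(com$committed_lineage), ]
    if (nrow(com)) {
        linOfCommitted <- tt$lineage[tt$founder_id %in% com$founder_id]
        expect_true(all(linOfCommitted == "PGC"))
    }

    cfg0 <- cleanConfig(nFounders = 10L, expansion = 20L, cellsSampled = 200L,
                        readsPerCell = 1, seed = 56L, inductionTime = "day0")
    sim0 <- simulateExperiment(cfg0, tinyDesign(2L), reads = FALSE)
    tt0 <- truthTable(sim0)
    # some founder pool is shared across lineages
    byFounder <- tapply(tt0$lineage, tt0$founder_id,
                        function(x) length(unique(x)))
    expect_gt(max(byFounder), 1L)
})

test_that("sampled lineage proportions match the configuration (chi-square)", {
    cfg <- cleanConfig(nFounders = 1500L, expansion = 8L,
                       cellsSampled = 10000L, readsPerCell = 1, seed = 77L)
    sim <- simulateExperiment(cfg, tinyDesign(2L), reads = FALSE)
    tab <- table(factor(sim$truth$cells$lineage, levels = EB_LINEAGES))
    p <- stats::chisq.test(tab, p = cfg@lineageProportions[EB_LINEAGES])$p.value
    expect_gt(p, 0.001)
})

test_that("every simulated founder barcode is reachable for its design", {
    d3 <- tinyDesign(3L)
    cfg <- cleanConfig(nFounders = 60L, expansion = 1L, cellsSampled = 60L,
                       readsPerCell = 1, seed = 12L)
    sim <- simulateExperiment(cfg, d3, reads = FALSE)
    expect_true(all(sim$truth$founders$polylox %in% enumerateBarcodes(d3)))
})

test_that("amplicons outside the purification window are dropped", {
    d <- tinyDesign(2L)
    cfg <- simConfig(nFounders = 4L, expansion = 2L, cellsSampled = 8L,
                     readsPerCell = 10, readsDispersion = Inf,
                     subRate = 0, insRate = 0, delRate = 0,
                     truncationProb = 0, contaminationRate = 0,
                     ampliconMin = 1e6, ampliconMax = Inf, seed = 3L)
    sim <- simulateExperiment(cfg, d)
    expect_length(sim$reads, 0L)
})

test_that("cell barcode whitelists respect the Hamming-distance floor", {
    set.seed(4)
    bc <- makeCellBarcodes(60, minDist = 3L)
    expect_identical(anyDuplicated(bc), 0L)
    m <- do.call(rbind, strsplit(bc, ""))
    for (i in 2:nrow(m)) {
        dmin <- min(rowSums(m[seq_len(i - 1L), , drop = FALSE] !=
                            rep(m[i, ], each = i - 1L)))
        expect_gte(dmin, 3L)
    }
})
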