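test_that("enrichedIntervals segments runs of enriched bins", {
    # constant track below tau -> empty
    flat <- manualTrack(rep(1, 20))
    expect_length(enrichedIntervals(flat, tau = 2), 0L)

    # one planted 50 kb run at bins 5..14 -> exactly that interval
    v <- rep(0, 20); v[5:14] <- 5
    tr <- manualTrack(v)
    out <- enrichedIntervals(tr, tau = 2)
    expect_length(out, 1L)
    expect_equal(start(out), 20001L)
    expect_equal(end(out), 70000L)

    # threshold is >=: bins exactly at tau count
    vt <- rep(0, 20); vt[3] <- 2
    expect_length(enrichedIntervals(manualTrack(vt), tau = 2), 1L)
})

test_that("merge gap boundary: gap == mergeGap merges, one bin more splits", {
    bw <- 5000
    # two runs separated by exactly one empty bin (5000 bp gap)
    v <- rep(0, 20); v[3:4] <- 5; v[6:7] <- 5
    tr <- manualTrack(v, binWidth = bw)
    merged <- enrichedIntervals(tr, tau = 2, mergeGap = bw)
    expect_length(merged, 1L)
    expect_equal(width(merged), 5L * bw)

    # gap of mergeGap + one bin width (two empty bins) stays split
    v2 <- rep(0, 20); v2[3:4] <- 5; v2[7:8] <- 5
    tr2 <- manualTrack(v2, binWidth = bw)
    split2 <- enrichedIntervals(tr2, tau = 2, mergeGap = bw)
    expect_length(split2, 2L)

    # mergeGap = 0 never merges across any gap
    split0 <- enrichedIntervals(tr, tau = 2, mergeGap = 0)
    expect_length(split0, 2L)
})

test_that("calls are the intersection of HP1 and H3K9me3 enrichment", {
    # planted truth in all three classes is recovered exactly
    b <- plainBundle(17, coloc = 1, noiseCV = 0,
                     counts = c(complex = 2, domain = 1, large_domain = 1),
                     len = 3e7)
    trs <- bundleTracks(b)
    calls <- callDomains(trs$HP1a, trs$H3K9me3)
    truth <- sort(bundleTruth(b))
    expect_length(calls, length(truth))
    expect_identical(ranges(calls), ranges(truth))
    expect_identical(as.character(calls$sizeClass),
                     as.character(truth$sizeClass))

    # an interval enriched in HP1 only produces no call there
    v <- rep(0, 40); v[11:20] <- 5
    hp1 <- manualTrack(v, mark = "HP1a")
    k9 <- manualTrack(rep(0.5, 40), mark = "H3K9me3")
    expect_length(callDomains(hp1, k9), 0L)

    expect_error(callDomains(list(), k9), "at least one HP1 track")
})

test_that("size classification uses half-open class edges", {
    # call of exactly 100,000 bp -> domain
    si <- testGenome(1e6)
    v <- rep(0, 20); v[2:3] <- 5            # 100 kb at 50 kb bins
    hp1 <- BinnedTrack(si, v, 50000L, "HP1a")
    k9 <- BinnedTrack(si, v, 50000L, "H3K9me3")
    calls <- callDomains(hp1, k9)
    expect_equal(width(calls), 100000L)
    expect_equal(as.character(calls$sizeClass), "domain")

    # one bp shorter -> complex (binWidth 99,999 makes it representable)
    si2 <- testGenome(999990)
    v2 <- rep(0, 10); v2[2] <- 5
    hp2 <- BinnedTrack(si2, v2, 99999L, "HP1a")
    k92 <- BinnedTrack(si2, v2, 99999L, "H3K9me3")
    calls2 <- callDomains(hp2, k92)
    expect_equal(width(calls2), 99999L)
    expect_equal(as.character(calls2$sizeClass), "complex")
})

test_that("exclude_mask drops calls masked over half their length", {
    si <- testGenome(1e6)
    bw <- 5000L
    v <- rep(0, 200)
    v[7:16] <- 5          # 30001..80000: 50 kb call, 20 kb masked (40%)
    v[101:112] <- 5       # 500001..560000: 60 kb call, 40 kb masked (67%)
    hp1 <- BinnedTrack(si, v, bw, "HP1a")
    k9 <- BinnedTrack(si, v, bw, "H3K9me3")
    mask <- GRanges("chrT", IRanges(c(60001, 520001), c(80000, 560000)),
                    seqinfo = si)
    whole <- callDomains(hp1, k9, mask = mask, mode = "whole_genome")
    expect_length(whole, 2L)
    kept <- callDomains(hp1, k9, mask = mask, mode = "exclude_mask")
    expect_length(kept, 1L)
    expect_equal(start(kept), 30001L)
    # any-overlap rule drops both
    none <- callDomains(hp1, k9, mask = mask, mode = "exclude_mask",
                        maskRule = "any")
    expect_length(none, 0L)
})

test_that("census summary counts classes and the 10-30 kb fraction", {
    si <- testGenome(2e7)
    mk <- function(widths, classes) {
        starts <- if (length(widths))
            cumsum(c(1, head(widths, -1) + 100000)) else integer(0)
        gr <- GRanges(rep("chrT", length(widths)),
                      IRanges(start = starts, width = widths),
                      seqinfo = si)
        gr$sizeClass <- factor(classes,
                               levels = c("complex", "domain",
                                          "large_domain"))
        gr
    }
    both <- mk(c(50000, 500000, 1500000),
               c("complex", "domain", "large_domain"))
    sm <- summarizeCalls(list(whole_genome = both, exclude_mask = both))
    expect_equal(unname(sm$counts[, "whole_genome"]), c(1L, 1L, 1L))
    expect_true(all(sm$counts[, "exclude_mask"] <=
                    sm$counts[, "whole_genome"]))

    # complexes of 12, 25, 80 kb -> fraction 2/3
    cx <- mk(c(12000, 25000, 80000), rep("complex", 3))
    sm2 <- summarizeCalls(list(whole_genome = cx))
    expect_equal(unname(sm2$fraction_10_30kb["whole_genome"]), 2 / 3)

    # empty call set: zero counts, flagged undefined fraction
    none <- mk(integer(0), character(0))
    sm3 <- summarizeCalls(list(whole_genome = none))
    expect_true(all(sm3$counts == 0L))
    expect_true(is.na(sm3$fraction_10_30kb["whole_genome"]))
    expect_false(sm3$has_complexes["whole_genome"])
})

test_that("raising tau never increases called bp; mergeGap never adds calls", {
    for (seed in c(3, 8)) {
        b <- plainBundle(seed, coloc = 1, noiseCV = 0.5,
                         counts = c(complex = 6, domain = 2))
        tr <- bundleTracks(b)$HP1a
        taus <- c(1.5, 2, 3, 5)
        bp <- vapply(taus, function(tau)
            sum(width(enrichedIntervals(tr, tau))), numeric(1))
        expect_true(all(diff(bp) <= 0))

        gaps <- c(0, 5000, 15000, 50000)
        ncalls <- vapply(gaps, function(g)
            length(enrichedIntervals(tr, 2, mergeGap = g)), numeric(1))
        expect_true(all(diff(ncalls) <= 0))
    }
})

test_that("exclude_mask counts never exceed whole-genome counts", {
    for (seed in c(5, 12, 19)) {
        b <- maskedBundle(seed, coloc = 1, noiseCV = 0.3)
        trs <- bundleTracks(b)
        byMode <- list(
            whole_genome = callDomains(trs$HP1a, trs$H3K9me3,
                                       mask = bundleMask(b),
                                       mode = "whole_genome"),
            exclude_mask = callDomains(trs$HP1a, trs$H3K9me3,
                                       mask = bundleMask(b),
                                       mode = "exclude_mask"))
        sm <- summarizeCalls(byMode)
        expect_true(all(sm$counts[, "exclude_mask"] <=
                        sm$counts[, "whole_genome"]))
    }
})

test_that("isoform union vs intersection combine rules behave as set ops", {
    v1 <- rep(0, 40); v1[5:10] <- 5
    v2 <- rep(0, 40); v2[8:14] <- 5
    k9v <- rep(0, 40); k9v[1:40] <- 5
    a <- manualTrack(v1, mark = "HP1a")
    bT <- manualTrack(v2, mark = "HP1b")
    k9 <- manualTrack(k9v, mark = "H3K9me3")
    p <- callerParams(minSize = 1e4)
    un <- callDomains(list(a, bT), k9, params = p, combine = "union")
    inter <- callDomains(list(a, bT), k9, params = p,
                         combine = "intersection")
    expect_equal(width(un), 50000L)       # bins 5..14
    expect_equal(width(inter), 15000L)    # bins 8..10
    expect_true(all(c("HP1a", "HP1b", "H3K9me3") %in%
                    unlist(un$marks)))
})
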