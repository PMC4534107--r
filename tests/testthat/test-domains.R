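## Per-base brute-force overlap oracles operate on chr1 within 1..10000.

test_that("segments map to genomic domains covering the CpG dinucleotides", {
    tr <- MethylomeTrack(rep("chr1", 3), c(101L, 201L, 301L),
                         M = c(9L, 8L, 10L), Cov = c(10L, 10L, 10L))
    seg1 <- peltSegment(methLevel(tr), 10)   # one segment
    dom <- buildDomains(tr, list(chr1 = seg1))
    expect_equal(length(dom), 1L)
    expect_equal(start(dom), 101L)
    expect_equal(end(dom), 302L)             # last CpG + dinucleotide
    expect_equal(width(dom), 202L)
    expect_equal(mcols(dom)$nCpG, 3L)
    expect_equal(mcols(dom)$meanMeth, 0.9)

    ## a changepoint after the first CpG: two domains abutting in CpG-index
    ## space but separated by a genomic gap
    seg2 <- dpSegment(c(0, 1, 1), penalty = 0.01)
    dom2 <- buildDomains(tr, list(chr1 = seg2))
    expect_equal(length(dom2), 2L)
    expect_equal(mcols(dom2)$nCpG, c(1L, 2L))
    expect_equal(start(dom2), c(101L, 201L))
    expect_equal(end(dom2), c(102L, 302L))

    expect_error(buildDomains(tr, list(chr1 = peltSegment(runif(9), 1))),
                 "sites")
})

test_that("domains partition the retained CpGs on random instances", {
    set.seed(21)
    for (i in 1:5) {
        sp <- alternatingSpec(nDomains = 6, lenRange = c(2000, 8000))
        sim <- simulateMethylome(sp, seed = i)
        tr <- filterByCoverage(sim$track, 5L)
        dom <- buildDomains(tr, segmentTrack(tr, penalty = 1))
        expect_equal(sum(mcols(dom)$nCpG), length(tr))
        expect_true(all(start(dom) < end(dom)))
        ## non-overlapping: merging only true overlaps conserves total bp
        expect_equal(sum(width(GenomicRanges::reduce(dom,
                                                     min.gapwidth = 0L))),
                     sum(width(dom)))
        ## weighted mean over domains reproduces the track-wide mean
        expect_equal(sum(mcols(dom)$meanMeth * mcols(dom)$nCpG) /
                         sum(mcols(dom)$nCpG),
                     mean(methLevel(tr)), tolerance = 1e-9)
    }
})

test_that("classification applies every matching label", {
    mk <- function(size, meth) {
        g <- GRanges("chr1", IRanges(1000L, width = size))
        mcols(g)$meanMeth <- meth
        g
    }
    lab <- function(size, meth)
        sort(unlist(mcols(classifyDomains(mk(size, meth)))$labels))
    expect_true("PMD" %in% lab(12000, 0.50))
    expect_true("DMV" %in% lab(6000, 0.10))
    expect_equal(lab(12000, 0.10), c("DMV", "PMD"))   # labels co-occur
    expect_equal(lab(500, 0.95), character())
    expect_equal(lab(2000, 0.05), "UMR")
    expect_equal(lab(1200, 0.30), "LMR")
    expect_equal(lab(50000, 0.95), "FMR")
})

test_that("loosening a rule threshold never removes a label", {
    set.seed(31)
    dom <- randomDomains(200)
    strict <- labelRulesFromList(list(
        X = list(min_size = 5000, max_meth = 0.5)))
    loose <- labelRulesFromList(list(
        X = list(min_size = 2000, max_meth = 0.7)))
    hasStrict <- lengths(mcols(classifyDomains(dom, strict))$labels) > 0
    hasLoose <- lengths(mcols(classifyDomains(dom, loose))$labels) > 0
    expect_true(all(hasLoose[hasStrict]))
})

test_that("overlap fractions match per-base counting", {
    d <- GRanges("chr1", IRanges(1, 100))
    mcols(d)$meanMeth <- 0.5
    expect_equal(overlapFraction(d, GRanges("chr1", IRanges(1, 100))), 1.0)
    expect_equal(overlapFraction(d, GRanges("chr1", IRanges(51, 200))), 0.5)
    expect_equal(suppressWarnings(
        overlapFraction(d, GRanges("chr2", IRanges(1, 100)))), 0.0)

    set.seed(41)
    for (i in 1:5) {
        doms <- randomRegions(8, 10000L)
        mcols(doms)$meanMeth <- runif(length(doms))
        regs <- randomRegions(12, 10000L)
        got <- overlapFraction(doms, regs)
        mask <- baseMask(regs, 10000L)
        want <- vapply(seq_along(doms), function(j)
            mean(mask[start(doms)[j]:end(doms)[j]]), numeric(1))
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("selection keeps domains with strictly more than the cutoff", {
    doms <- GRanges("chr1", IRanges(c(1, 201, 401), width = 100))
    mcols(doms)$meanMeth <- c(0.1, 0.5, 0.9)
    regs <- GRanges("chr1", IRanges(c(1, 201, 401),
                                    width = c(100, 81, 80)))
    sel <- selectOverlapping(doms, regs, minFraction = 0.8)
    expect_equal(start(sel), c(1L, 201L))    # 1.0 and 0.81 pass, 0.80 fails
})

test_that("reciprocal region coverage matches per-base counting", {
    a <- GRanges("chr1", IRanges(c(1, 500), width = 100))
    expect_equal(unname(regionCoverage(a, a)), c(1, 1))
    b <- GRanges("chr1", IRanges(2000, width = 50))
    expect_equal(unname(regionCoverage(a, b)), c(0, 0))

    set.seed(43)
    for (i in 1:5) {
        ra <- randomRegions(10, 10000L)
        rb <- randomRegions(10, 10000L)
        got <- regionCoverage(ra, rb)
        ma <- baseMask(ra, 10000L); mb <- baseMask(rb, 10000L)
        expect_equal(unname(got),
                     c(sum(ma & mb) / sum(ma), sum(ma & mb) / sum(mb)),
                     tolerance = 1e-12)
    }
})

test_that("DMR calling reports atoms with diverged levels", {
    mkdom <- function(starts, ends, meth, ncpg = 10L) {
        g <- GRanges("chr1", IRanges(starts, ends))
        mcols(g)$nCpG <- rep(ncpg, length(g))
        mcols(g)$meanMeth <- meth
        g
    }
    a <- mkdom(c(1, 1001), c(1000, 2000), c(0.9, 0.1))

    expect_equal(length(detectDMRs(a, a)), 0L)

    b <- mkdom(c(1, 1001), c(1000, 2000), c(0.9, 0.8))
    d1 <- detectDMRs(a, b, minLevelDiff = 0.3)
    expect_equal(start(d1), 1001L)
    expect_equal(end(d1), 2000L)
    expect_equal(mcols(d1)$meanA, 0.1)
    expect_equal(mcols(d1)$meanB, 0.8)

    ## one shared domain, fully diverged levels
    u <- mkdom(1, 2000, 0.9)
    v <- mkdom(1, 2000, 0.1)
    d2 <- detectDMRs(u, v)
    expect_equal(c(start(d2), end(d2)), c(1L, 2000L))
    expect_equal(mcols(d2)$diff, 0.8)

    ## boundary shift: only the non-shared piece is a DMR
    A <- mkdom(c(1, 1001), c(1000, 2000), c(0.9, 0.1))
    B <- mkdom(c(1, 1501), c(1500, 2000), c(0.9, 0.1))
    d3 <- detectDMRs(A, B)
    expect_equal(start(d3), 1001L)
    expect_equal(end(d3), 1500L)
    expect_equal(mcols(d3)$meanA, 0.1)
    expect_equal(mcols(d3)$meanB, 0.9)
})

test_that("abutting diverged atoms merge into one DMR with weighted means", {
    mkdom <- function(starts, ends, meth, ncpg) {
        g <- GRanges("chr1", IRanges(starts, ends))
        mcols(g)$nCpG <- ncpg
        mcols(g)$meanMeth <- meth
        g
    }
    ## A has one 0.9 domain over 1..2000; B splits it into two low domains
    a <- mkdom(1, 2000, 0.9, 40L)
    b <- mkdom(c(1, 1001), c(1000, 2000), c(0.1, 0.3), c(30L, 10L))
    d <- detectDMRs(a, b)
    expect_equal(length(d), 1L)
    expect_equal(c(start(d), end(d)), c(1L, 2000L))
    expect_equal(mcols(d)$meanA, 0.9)
    expect_equal(mcols(d)$meanB, (30 * 0.1 + 10 * 0.3) / 40)
})
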