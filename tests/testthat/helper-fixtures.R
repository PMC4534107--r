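## Shared fixture builders.  Everything is generated in code; no data files.

## Write a small Bismark CpG report (1-based, per-strand rows).
writeBismarkFixture <- function(lines, path = tempfile(fileext = ".txt")) {
    writeLines(lines, path)
    path
}

## A 10-CpG plus-strand Bismark report with deterministic counts.
tenLineBismark <- function(path = tempfile(fileext = ".txt")) {
    pos <- seq(101L, by = 50L, length.out = 10L)
    m <- c(3L, 5L, 0L, 7L, 2L, 9L, 4L, 1L, 6L, 8L)
    u <- c(2L, 0L, 6L, 1L, 5L, 0L, 3L, 7L, 2L, 1L)
    writeLines(sprintf("chr1\t%d\t+\t%d\t%d\tCpG\tCGA", pos, m, u), path)
    path
}

## Random domain GRanges for MDL/overlap tests.
randomDomains <- function(n, chrom = "chr1", maxPos = 1e6L) {
    start <- sort(sample.int(maxPos, n))
    width <- sample(50:20000, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start, width = width))
    GenomicRanges::mcols(gr)$meanMeth <- stats::runif(n)
    GenomicRanges::mcols(gr)$nCpG <- sample(1:200, n, replace = TRUE)
    gr
}

## Random non-overlapping region set on a small interval, for per-base
## brute-force overlap oracles.
randomRegions <- function(n, maxPos = 10000L) {
    s <- sort(sample.int(maxPos - 50L, n))
    e <- pmin(s + sample(10:500, n, replace = TRUE), maxPos)
    GenomicRanges::reduce(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e)))
}

## Per-base occupancy vector of a GRanges on chr1 over 1..maxPos.
baseMask <- function(gr, maxPos) {
    v <- logical(maxPos)
    for (i in seq_along(gr)) {
        a <- max(1L, GenomicRanges::start(gr)[i])
        b <- min(maxPos, GenomicRanges::end(gr)[i])
        if (a <= b) v[a:b] <- TRUE
    }
    v
}

## A track with given per-site coverage on chr1 at fixed spacing.
trackFromCounts <- function(M, Cov, spacing = 10L) {
    n <- length(Cov)
    MethylomeTrack(rep("chr1", n), seq(1L, by = spacing, length.out = n),
                   as.integer(M), as.integer(Cov))
}

## Whole-genome-like spec: domains with log-uniform sizes in [1, 30] kb and
## alternating high/low methylation, filling `genomeLength` bp.  Used for
## the data-size robustness trend (call set.seed before this).
genomeSpec <- function(genomeLength = 1e7, depth = 30) {
    sizes <- round(10^stats::runif(ceiling(genomeLength / 2000), 3,
                                   log10(3e4)))
    n <- which(cumsum(sizes) >= genomeLength)[1L]
    if (is.na(n)) n <- length(sizes)
    sizes <- sizes[seq_len(n)]
    k <- length(sizes)
    lows <- stats::runif(ceiling(k / 2), 0, 0.3)
    highs <- stats::runif(ceiling(k / 2), 0.65, 1)
    pi <- as.vector(rbind(highs, lows))[seq_len(k)]
    simSpec(data.frame(chrom = "chr1", length = sizes, pi = pi),
            meanSpacing = 100, depth = depth)
}

## Spec for a multi-domain genome with alternating high/low levels whose
## neighbouring domains differ by at least `minDelta`.
alternatingSpec <- function(nDomains, lenRange = c(6000, 12000),
                            minDelta = 0.3, depth = 30,
                            meanSpacing = 100) {
    lows <- stats::runif(ceiling(nDomains / 2), 0, 0.3)
    highs <- stats::runif(ceiling(nDomains / 2), 0.65, 1)
    pi <- as.vector(rbind(highs, lows))[seq_len(nDomains)]
    stopifnot(all(abs(diff(pi)) >= minDelta))
    simSpec(data.frame(chrom = "chr1",
                       length = round(stats::runif(nDomains, lenRange[1],
                                                   lenRange[2])),
                       pi = pi),
            meanSpacing = meanSpacing, depth = depth)
}
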