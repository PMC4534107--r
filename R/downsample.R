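#' Thin read counts to emulate a smaller sequencing run
#'
#' Retains each read independently with probability \code{fraction}.
#' Modeled at the count level: the new total at a site is
#' Binomial(Cov, fraction) and the new methylated count is drawn
#' hypergeometrically from the site's reads, which is distributionally
#' identical to per-read Bernoulli retention.  Thinning is unbiased for
#' the methylation level: E[new M / new Cov | new Cov > 0] equals the
#' original level in expectation.  Sites whose thinned coverage is zero
#' are dropped.
#'
#' @param x A \linkS4class{MethylomeTrack}.
#' @param fraction Retention probability in (0, 1].  \code{fraction = 1}
#'   returns the track unchanged.
#' @param seed Optional integer seed for reproducibility.
#' @return A thinned \linkS4class{MethylomeTrack}.
#' @examples
#' tr <- MethylomeTrack(rep("chr1", 3), c(11L, 21L, 31L),
#'                      c(5L, 2L, 8L), c(10L, 10L, 10L))
#' thinCounts(tr, 0.5, seed = 1L)
#' @rdname thinCounts
#' @export
setMethod("thinCounts", "MethylomeTrack", function(x, fraction,
                                                   seed = NULL) {
    stopifnot(length(fraction) == 1L, is.finite(fraction))
    if (fraction <= 0 || fraction > 1)
        stop("fraction must be in (0, 1]")
    if (fraction == 1) return(x)
    if (!is.null(seed)) set.seed(seed)
    gr <- sites(x)
    m <- mcols(gr)$M
    cov <- mcols(gr)$Cov
    newCov <- stats::rbinom(length(gr), cov, fraction)
    newM <- stats::rhyper(length(gr), m = m, n = cov - m, k = newCov)
    keep <- newCov > 0L
    MethylomeTrack(as.character(seqnames(gr))[keep], start(gr)[keep],
                   newM[keep], newCov[keep],
                   sampleName = x@sampleName, minDepth = 1)
})
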