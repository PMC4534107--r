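#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqlevelsInUse seqlevels
#' @importFrom Rcpp sourceCpp
#' @useDynLib MethylScape, .registration = TRUE
NULL

#' MethylomeTrack: per-CpG methylation calls for one sample
#'
#' Ordered per-chromosome collection of CpG sites, each carrying the number
#' of methylated calls (\code{M}) and the total read coverage (\code{Cov}).
#' Sites are width-1 \linkS4class{GRanges} positions anchored at the C of
#' the CpG on the plus strand (counts from the two strands of one CpG are
#' merged at read time).  The methylation level of a site is \code{M/Cov}.
#'
#' @slot sites A \linkS4class{GRanges} of width-1 positions, sorted, with
#'   integer metadata columns \code{M} and \code{Cov} (\code{0 <= M <= Cov},
#'   \code{Cov >= 1}; zero-coverage sites are dropped on construction).
#' @slot sampleName Character scalar sample identifier.
#' @slot minDepth The coverage threshold already applied to the track
#'   (1 if unfiltered).
#'
#' @seealso [readMethylome()], [filterByCoverage()], [callDomains()]
#' @export
setClass("MethylomeTrack",
    slots = c(sites = "GRanges",
              sampleName = "character",
              minDepth = "numeric"))

setValidity("MethylomeTrack", function(object) {
    gr <- object@sites
    msg <- character()
    mc <- mcols(gr)
    if (!all(c("M", "Cov") %in% colnames(mc)))
        return("sites must carry 'M' and 'Cov' metadata columns")
    if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "all sites must have width 1")
        if (any(mc$M < 0L) || any(mc$Cov < 1L) || any(mc$M > mc$Cov))
            msg <- c(msg, "need 0 <= M <= Cov and Cov >= 1 at every site")
        bychr <- split(start(gr), as.character(seqnames(gr)))
        if (any(vapply(bychr, function(p) is.unsorted(p, strictly = TRUE),
                       logical(1))))
            msg <- c(msg, "positions must be strictly increasing per chromosome")
    }
    if (length(object@sampleName) != 1L)
        msg <- c(msg, "sampleName must be a single string")
    if (length(object@minDepth) != 1L || object@minDepth < 1)
        msg <- c(msg, "minDepth must be a single value >= 1")
    if (length(msg)) msg else TRUE
})

#' Segmentation: changepoints of one numeric series
#'
#' Result of exact penalized least-squares segmentation of a single series
#' (one chromosome's CpG methylation levels, in CpG-ordinal space).
#' Changepoints are last indices of segments: changepoints \code{t_1 < ... <
#' t_m} split \code{1..n} into \code{[1, t_1], [t_1+1, t_2], ...,
#' [t_m+1, n]}.  The objective is the sum of per-segment costs (sum of
#' squared deviations from the segment mean) plus \code{penalty * m}.
#'
#' @slot changepoints Integer vector, strictly increasing, each in
#'   \code{[1, n)}.
#' @slot segMean Numeric vector of per-segment means.
#' @slot segCost Numeric vector of per-segment least-squares costs.
#' @slot segStart,segEnd Integer vectors of segment bounds (1-based,
#'   inclusive).
#' @slot penalty The penalty used.
#' @slot objective Total penalized objective.
#' @slot n Series length.
#'
#' @seealso [peltSegment()], [dpSegment()]
#' @export
setClass("Segmentation",
    slots = c(changepoints = "integer",
              segMean = "numeric",
              segCost = "numeric",
              segStart = "integer",
              segEnd = "integer",
              penalty = "numeric",
              objective = "numeric",
              n = "integer"))

setValidity("Segmentation", function(object) {
    msg <- character()
    n <- object@n
    cp <- object@changepoints
    if (length(cp) && (is.unsorted(cp, strictly = TRUE) ||
                       any(cp < 1L) || any(cp >= n)))
        msg <- c(msg, "changepoints must be strictly increasing in [1, n)")
    k <- length(cp) + 1L
    if (length(object@segMean) != k || length(object@segCost) != k ||
        length(object@segStart) != k || length(object@segEnd) != k)
        msg <- c(msg, "per-segment slots must have length m + 1")
    if (!identical(object@segStart, c(1L, cp + 1L)) ||
        !identical(object@segEnd, c(cp, n)))
        msg <- c(msg, "segments must partition 1..n at the changepoints")
    if (length(msg)) msg else TRUE
})

#' MDLMatrix: methylated domain landscape count grid
#'
#' A fixed-grid 2D histogram of methylated domains over (log10 domain size,
#' mean methylation level).  Rows are methylation-level bins (low to high),
#' columns are size bins (small to large).  The default grid has 20 x 20 =
#' 400 pixels spanning [100 bp, 1e7 bp] x [0, 1]; domains falling outside
#' the grid are tallied in \code{outOfRange}, never silently dropped, so
#' \code{sum(counts) + outOfRange} always equals the number of input
#' domains.
#'
#' @slot counts Integer matrix of pixel counts (meth bins x size bins).
#' @slot sizeEdges Numeric vector of bin edges in bp (length nbins + 1,
#'   geometric by default).
#' @slot methEdges Numeric vector of methylation-level bin edges.
#' @slot total Number of domains binned inside the grid.
#' @slot outOfRange Number of domains outside the grid.
#' @slot sampleName Sample identifier.
#'
#' @seealso [computeMDL()], [mdlVector()], [spearmanMatrix()]
#' @export
setClass("MDLMatrix",
    slots = c(counts = "matrix",
              sizeEdges = "numeric",
              methEdges = "numeric",
              total = "integer",
              outOfRange = "integer",
              sampleName = "character"))

setValidity("MDLMatrix", function(object) {
    msg <- character()
    nm <- length(object@methEdges) - 1L
    ns <- length(object@sizeEdges) - 1L
    if (!identical(dim(object@counts), c(nm, ns)))
        msg <- c(msg, "counts must be (meth bins) x (size bins)")
    if (is.unsorted(object@sizeEdges, strictly = TRUE) ||
        is.unsorted(object@methEdges, strictly = TRUE))
        msg <- c(msg, "bin edges must be strictly increasing")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (sum(object@counts) != object@total)
        msg <- c(msg, "total must equal sum(counts)")
    if (length(msg)) msg else TRUE
})
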