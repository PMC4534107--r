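## Penalized least-squares changepoint detection.
##
## The model: a series X_1..X_N of CpG methylation levels is piecewise
## constant in mean; the cost of a candidate segment is the sum of squared
## deviations from its mean,
##     C(k:n) = sum_{i=k..n} (X_i - mu)^2 ,
## and a segmentation is scored by  sum(segment costs) + beta * m  with m
## changepoints.  A split at t is accepted only when it lowers the total,
## i.e.  C(1:N) > C(1:t) + C(t+1:N) + beta.  The penalty beta is a FIXED
## constant, deliberately independent of series length, so that detection
## sensitivity is identical on every chromosome regardless of its size.
## Genomic distance between CpGs is ignored: the series index is the CpG
## ordinal, and each chromosome is segmented independently.

.checkSeries <- function(x) {
    if (length(x) < 1L) stop("empty series")
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
        stop("series values must be finite numbers")
    as.numeric(x)
}

.makeSegmentation <- function(x, cp, penalty) {
    n <- length(x)
    cp <- as.integer(cp)
    segStart <- c(1L, cp + 1L)
    segEnd <- c(cp, n)
    segMean <- numeric(length(segStart))
    segCost <- numeric(length(segStart))
    for (j in seq_along(segStart)) {
        v <- x[segStart[j]:segEnd[j]]
        segMean[j] <- mean(v)
        segCost[j] <- sum((v - segMean[j])^2)
    }
    new("Segmentation", changepoints = cp, segMean = segMean,
        segCost = segCost, segStart = segStart, segEnd = segEnd,
        penalty = penalty, objective = sum(segCost) + penalty * length(cp),
        n = n)
}

#' Least-squares cost of one segment
#'
#' Computes \code{C(k:n) = sum((x[k:n] - mean(x[k:n]))^2)}, the
#' change-in-mean cost used throughout the segmentation, from prefix sums
#' of \code{x} and \code{x^2} (O(1) per query after O(N) setup when called
#' through [peltSegment()]/[dpSegment()]).
#'
#' @param x Numeric series.
#' @param k,n Start and end indices (1-based, inclusive), \code{k <= n}.
#' @return The segment cost (dimensionless, >= 0 up to rounding).
#' @examples
#' segmentCost(c(0, 0, 0, 1, 1, 1), 1, 6)  # 1.5
#' @export
segmentCost <- function(x, k, n) {
    x <- .checkSeries(x)
    if (k > n) stop("k > n")
    if (k < 1L || n > length(x)) stop("indices out of range")
    S1 <- c(0, cumsum(x))
    S2 <- c(0, cumsum(x^2))
    s <- S1[n + 1L] - S1[k]
    (S2[n + 1L] - S2[k]) - s * s / (n - k + 1L)
}

#' Exact penalized segmentation by PELT
#'
#' Finds the segmentation of \code{x} minimizing the penalized
#' least-squares objective (sum of per-segment costs plus \code{penalty}
#' per changepoint) with the Pruned Exact Linear Time recursion.  Because
#' the cost is nonnegative, pruning with constant K = 0 is exact: the
#' result has the same objective as exhaustive optimization (see
#' [dpSegment()]).  Ties between split points are broken toward the
#' smallest index, and a cost-neutral split is not made.
#'
#' @param x Numeric series of methylation levels (one chromosome, ordered
#'   by CpG ordinal).
#' @param penalty Fixed penalty beta >= 0 per changepoint; default 1.0, a
#'   practical balance between sensitivity and specificity for WGBS
#'   methylation levels in [0, 1].
#' @return A \linkS4class{Segmentation}.
#' @examples
#' s <- peltSegment(c(0, 0, 0, 1, 1, 1), penalty = 1)
#' changepoints(s)  # 3
#' @seealso [dpSegment()] for the unpruned O(N^2) recursion,
#'   [maxPenaltyScan()] for per-boundary reliability.
#' @export
peltSegment <- function(x, penalty = 1.0) {
    x <- .checkSeries(x)
    stopifnot(length(penalty) == 1L, penalty >= 0)
    res <- .pelt_cpp(x, penalty)
    .makeSegmentation(x, res$changepoints, penalty)
}

#' Exact penalized segmentation by full dynamic programming
#'
#' The standard O(N^2) optimal-partition recursion with no pruning.  Same
#' contract and tie-breaking as [peltSegment()]; kept as an independent
#' reference implementation for cross-checking on small series.
#'
#' @inheritParams peltSegment
#' @return A \linkS4class{Segmentation}.
#' @export
dpSegment <- function(x, penalty = 1.0) {
    x <- .checkSeries(x)
    stopifnot(length(penalty) == 1L, penalty >= 0)
    n <- length(x)
    S1 <- c(0, cumsum(x))
    S2 <- c(0, cumsum(x^2))
    F <- c(-penalty, rep(NA_real_, n))
    prev <- integer(n)
    for (s in seq_len(n)) {
        t <- 0:(s - 1L)                       # candidate last changepoints
        w <- s - t
        sm <- S1[s + 1L] - S1[t + 1L]
        cost <- (S2[s + 1L] - S2[t + 1L]) - sm * sm / w
        vals <- F[t + 1L] + cost + penalty
        best <- which.min(vals)               # first minimum: smallest t
        F[s + 1L] <- vals[best]
        prev[s] <- t[best]
    }
    cps <- integer()
    t <- prev[n]
    while (t > 0L) { cps <- c(t, cps); t <- prev[t] }
    .makeSegmentation(x, cps, penalty)
}

#' @describeIn Segmentation-class Changepoint indices (last index of each
#'   segment but the final one).
#' @export
setMethod("changepoints", "Segmentation", function(x) x@changepoints)

#' @rdname Segmentation-class
#' @export
setMethod("length", "Segmentation", function(x) length(x@changepoints) + 1L)

setMethod("show", "Segmentation", function(object) {
    cat("Segmentation: N =", object@n, ", penalty =", object@penalty,
        ",", length(object@changepoints), "changepoint(s), objective =",
        format(object@objective, digits = 6), "\n")
    if (length(object@changepoints))
        cat("  changepoints:",
            paste(utils::head(object@changepoints, 10L), collapse = ", "),
            if (length(object@changepoints) > 10L) "...", "\n")
})

#' Maximum penalty at which each boundary is still detected
#'
#' Re-runs the segmentation over a descending grid of penalties and, for
#' every boundary that appears in any of the segmentations, reports the
#' largest grid penalty whose segmentation still contains it.  The value
#' acts as a reliability score for the boundary: boundaries separating
#' large or strongly contrasting domains survive high penalties, marginal
#' boundaries vanish early.  Boundaries never detected on the grid are
#' absent from the result.
#'
#' @param x Numeric series.
#' @param penaltyGrid Positive penalties to scan; default a 25-point
#'   geometric grid from 0.05 to 50.
#' @return A named numeric vector mapping boundary index (as character) to
#'   its maximum detecting grid penalty, ordered by boundary index.
#' @examples
#' maxPenaltyScan(c(0, 0, 0, 1, 1, 1), c(1.4, 1.0, 0.5))  # 3 -> 1.4
#' @export
maxPenaltyScan <- function(x, penaltyGrid = defaultPenaltyGrid()) {
    x <- .checkSeries(x)
    if (length(penaltyGrid) == 0L) stop("empty penalty grid")
    if (any(penaltyGrid <= 0)) stop("penalty grid must be strictly positive")
    grid <- sort(unique(penaltyGrid), decreasing = TRUE)
    out <- numeric(0)
    for (beta in grid) {
        cp <- changepoints(peltSegment(x, beta))
        newcp <- setdiff(cp, as.integer(names(out)))
        if (length(newcp))
            out[as.character(newcp)] <- beta
    }
    out[order(as.integer(names(out)))]
}

#' Default penalty grid for [maxPenaltyScan()]
#'
#' A 25-point geometric grid spanning 0.05 to 50, covering penalties from
#' very permissive (many tiny domains) to very strict (only the strongest
#' boundaries).
#'
#' @return Ascending numeric vector of length 25.
#' @export
defaultPenaltyGrid <- function() {
    10^seq(log10(0.05), log10(50), length.out = 25L)
}

#' Segment every chromosome of a methylome track
#'
#' Runs [peltSegment()] independently on each chromosome's ordered
#' methylation levels.  A changepoint can never span a chromosome
#' boundary.
#'
#' @param track A \linkS4class{MethylomeTrack} (already coverage-filtered
#'   as desired).
#' @param penalty Fixed penalty per changepoint (default 1.0).
#' @return Named list of \linkS4class{Segmentation}, one per chromosome in
#'   use.
#' @seealso [buildDomains()], [callDomains()]
#' @export
segmentTrack <- function(track, penalty = 1.0) {
    stopifnot(is(track, "MethylomeTrack"))
    gr <- sites(track)
    lv <- methLevel(track)
    chroms <- seqlevelsInUse(gr)
    out <- vector("list", length(chroms))
    names(out) <- chroms
    chr <- as.character(seqnames(gr))
    for (cn in chroms)
        out[[cn]] <- peltSegment(lv[chr == cn], penalty)
    out
}
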