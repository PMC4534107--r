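## Synthetic methylomes with known domain structure.
##
## The generator realizes the piecewise-constant-mean model underlying the
## segmentation: the genome is a sequence of domains, each with a true
## methylation probability pi; CpG positions are placed with geometric
## inter-CpG gaps (optionally 10x denser inside designated "island"
## domains, mimicking the CpG-density contrast between unmethylated
## islands and CpG-poor low-methylated regions); per-site coverage is
## Poisson and methylated counts are Binomial(Cov, pi).

#' Specification of a synthetic methylome
#'
#' @param domains A data.frame with columns \code{chrom}, \code{length}
#'   (bp, positive), \code{pi} (true methylation level in [0, 1]) and
#'   optionally \code{island} (logical: CpG-dense domain).  Rows are laid
#'   end to end along each chromosome in order.
#' @param meanSpacing Mean inter-CpG distance in bp outside islands
#'   (default 100, a typical genome-wide CpG spacing).
#' @param islandFactor Density multiplier inside island domains (default
#'   10).
#' @param depth Mean Poisson read coverage per site (default 30, deep
#'   WGBS).
#' @param sampleName Sample identifier for the generated track.
#' @return A list of class \code{"SimSpec"}.
#' @seealso [simulateMethylome()]
#' @export
simSpec <- function(domains, meanSpacing = 100, islandFactor = 10,
                    depth = 30, sampleName = "sim") {
    stopifnot(is.data.frame(domains),
              all(c("chrom", "length", "pi") %in% names(domains)),
              nrow(domains) >= 1L,
              all(domains$length > 0),
              all(domains$pi >= 0 & domains$pi <= 1),
              meanSpacing > 2, islandFactor >= 1, depth > 0)
    if (is.null(domains$island)) domains$island <- FALSE
    structure(list(domains = domains, meanSpacing = meanSpacing,
                   islandFactor = islandFactor, depth = depth,
                   sampleName = sampleName),
              class = "SimSpec")
}

.simPositions <- function(len, spacing, seed = NULL) {
    ## strictly increasing offsets in [1, len]; gaps >= 2 so CpGs never
    ## overlap, geometric tail with mean gap == spacing
    p <- 1 / (spacing - 1)
    n <- ceiling(len / spacing * 1.6) + 25L
    gaps <- 2L + stats::rgeom(n, p)
    pos <- cumsum(gaps)
    pos <- pos[pos <= len]
    while (length(pos) && (len - pos[length(pos)]) > 40 * spacing) {
        extra <- pos[length(pos)] + cumsum(2L + stats::rgeom(n, p))
        pos <- c(pos, extra[extra <= len])
    }
    pos
}

#' Simulate a methylome with known domain structure
#'
#' @param spec A [simSpec()] object.
#' @param seed Integer seed; the same seed always yields the same track.
#' @return A list with elements \code{track} (a
#'   \linkS4class{MethylomeTrack}; zero-coverage sites already dropped)
#'   and \code{truth}, itself a list with \code{domains} (a
#'   \linkS4class{GRanges} with the true \code{pi}) and \code{boundaries}
#'   (a data.frame \code{chrom}, \code{pos}: 1-based genomic start of
#'   every internal true domain boundary).
#' @examples
#' sp <- simSpec(data.frame(chrom = "chr1", length = c(1e4, 1e4),
#'                          pi = c(0.9, 0.1)))
#' sim <- simulateMethylome(sp, seed = 7L)
#' sim$truth$boundaries
#' @export
simulateMethylome <- function(spec, seed = NULL) {
    stopifnot(inherits(spec, "SimSpec"))
    if (!is.null(seed)) set.seed(seed)
    dom <- spec$domains
    chromv <- character(); posv <- integer()
    mv <- integer(); covv <- integer()
    tchrom <- character(); tstart <- integer(); tend <- integer()
    tpi <- numeric()
    bchrom <- character(); bpos <- integer()
    for (cn in unique(dom$chrom)) {
        d <- dom[dom$chrom == cn, , drop = FALSE]
        offset <- 0L
        for (j in seq_len(nrow(d))) {
            spacing <- spec$meanSpacing /
                (if (isTRUE(d$island[j])) spec$islandFactor else 1)
            off <- .simPositions(d$length[j], spacing)
            if (length(off)) {
                pos <- offset + off
                cov <- stats::rpois(length(pos), spec$depth)
                m <- stats::rbinom(length(pos), cov, d$pi[j])
                keep <- cov > 0L
                chromv <- c(chromv, rep(cn, sum(keep)))
                posv <- c(posv, pos[keep])
                mv <- c(mv, m[keep])
                covv <- c(covv, cov[keep])
            }
            tchrom <- c(tchrom, cn)
            tstart <- c(tstart, offset + 1L)
            tend <- c(tend, offset + as.integer(d$length[j]))
            tpi <- c(tpi, d$pi[j])
            if (j > 1L) {
                bchrom <- c(bchrom, cn)
                bpos <- c(bpos, offset + 1L)
            }
            offset <- offset + as.integer(d$length[j])
        }
    }
    truthDom <- GRanges(tchrom, IRanges(tstart, tend))
    mcols(truthDom)$pi <- tpi
    track <- MethylomeTrack(chromv, posv, mv, covv,
                            sampleName = spec$sampleName)
    list(track = track,
         truth = list(domains = truthDom,
                      boundaries = data.frame(chrom = bchrom, pos = bpos)))
}

#' Write the true domains of a simulation as BED4
#'
#' @param truth The \code{truth} element of [simulateMethylome()] output.
#' @param path Output BED path (0-based half-open; name column carries the
#'   true pi).
#' @return \code{path}, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    d <- truth$domains
    df <- data.frame(chrom = as.character(seqnames(d)),
                     start = start(d) - 1L,
                     end = end(d),
                     name = paste0("pi=", mcols(d)$pi))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.boundaryOrdinals <- function(positions, bpos) {
    ## ordinal of a genomic boundary b: number of retained sites strictly
    ## before b (so a boundary between site i and i+1 has ordinal i)
    findInterval(bpos - 0.5, positions)
}

#' Boundary recovery of a segmentation against simulation truth
#'
#' Matches predicted domain boundaries (left edges of all but the first
#' domain per chromosome) against true boundaries, measuring distance in
#' retained CpG sites: both are mapped to CpG ordinals on the filtered
#' track and matched greedily one-to-one by increasing ordinal distance,
#' accepting only pairs within \code{toleranceCpG} sites.
#'
#' @param truth The \code{truth} element of [simulateMethylome()] output.
#' @param domains Predicted domain \linkS4class{GRanges} (from
#'   [buildDomains()]/[callDomains()]).
#' @param track The filtered \linkS4class{MethylomeTrack} that was
#'   segmented (defines the CpG ordinals).
#' @param toleranceCpG Maximum matching distance in retained CpG sites
#'   (default 2).
#' @return Named numeric vector \code{c(recall, precision)}: recovered
#'   true boundaries / total true, and matched predicted boundaries /
#'   total predicted.  With no predicted boundaries precision is reported
#'   as 1 by convention (nothing asserted, nothing wrong).
#' @export
boundaryRecovery <- function(truth, domains, track, toleranceCpG = 2L) {
    gr <- sites(track)
    chr <- as.character(seqnames(gr))
    dchr <- as.character(seqnames(domains))
    tb <- truth$boundaries
    nTrue <- 0L; nPred <- 0L; nMatch <- 0L
    for (cn in unique(c(tb$chrom, dchr))) {
        positions <- start(gr)[chr == cn]
        trueOrd <- .boundaryOrdinals(positions, tb$pos[tb$chrom == cn])
        di <- which(dchr == cn)
        predPos <- if (length(di) > 1L) start(domains)[di[-1L]] else integer()
        predOrd <- .boundaryOrdinals(positions, predPos)
        nTrue <- nTrue + length(trueOrd)
        nPred <- nPred + length(predOrd)
        nMatch <- nMatch + .greedyMatch(trueOrd, predOrd, toleranceCpG)
    }
    c(recall = if (nTrue) nMatch / nTrue else 1,
      precision = if (nPred) nMatch / nPred else 1)
}

.greedyMatch <- function(a, b, tol) {
    ## one-to-one greedy matching by increasing |distance|, ties broken by
    ## (a index, b index); returns the number of matched pairs within tol
    if (!length(a) || !length(b)) return(0L)
    pairs <- expand.grid(i = seq_along(a), j = seq_along(b))
    pairs$d <- abs(a[pairs$i] - b[pairs$j])
    pairs <- pairs[pairs$d <= tol, , drop = FALSE]
    if (!nrow(pairs)) return(0L)
    pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
    usedA <- logical(length(a)); usedB <- logical(length(b))
    n <- 0L
    for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE; usedB[j] <- TRUE; n <- n + 1L
        }
    }
    n
}
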