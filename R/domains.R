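## Methylated domains: genomic intervals obtained by mapping per-chromosome
## changepoints (in CpG-ordinal space) back onto genomic coordinates.

#' Map segmentations back onto genomic coordinates
#'
#' Converts per-chromosome \linkS4class{Segmentation} objects into domains:
#' one genomic interval per segment, running from the position of the
#' segment's first CpG to the position of its last CpG plus one (so the
#' interval covers the terminal CpG dinucleotide).  Gaps between the last
#' CpG of a chromosome and the chromosome end carry no data and receive no
#' domain.
#'
#' @param track The \linkS4class{MethylomeTrack} that was segmented.
#' @param segmentations Named list of \linkS4class{Segmentation} as
#'   returned by [segmentTrack()]; names are chromosomes, and each
#'   segmentation's \code{n} must equal the number of retained sites on
#'   that chromosome.
#' @return A sorted \linkS4class{GRanges} with metadata columns
#'   \code{nCpG} (sites per domain) and \code{meanMeth} (arithmetic mean of
#'   member site levels).  Within a chromosome, domains partition the
#'   retained CpGs: \code{sum(nCpG)} equals the retained site count.
#' @seealso [callDomains()] for the one-call pipeline.
#' @export
buildDomains <- function(track, segmentations) {
    stopifnot(is(track, "MethylomeTrack"), is.list(segmentations))
    gr <- sites(track)
    lv <- methLevel(track)
    chr <- as.character(seqnames(gr))
    pieces <- list()
    for (cn in names(segmentations)) {
        seg <- segmentations[[cn]]
        idx <- which(chr == cn)
        if (seg@n != length(idx))
            stop("segmentation for ", cn, " has n = ", seg@n,
                 " but the track holds ", length(idx), " sites")
        pos <- start(gr)[idx]
        s <- seg@segStart
        e <- seg@segEnd
        d <- GRanges(cn, IRanges(pos[s], pos[e] + 1L))
        mcols(d)$nCpG <- e - s + 1L
        mcols(d)$meanMeth <- seg@segMean
        pieces[[cn]] <- d
    }
    if (!length(pieces)) return(GRanges())
    out <- do.call(c, unname(pieces))
    sort(out, ignore.strand = TRUE)
}

#' One-call methylome-to-domains pipeline
#'
#' Coverage-filters a methylome track, segments every chromosome with a
#' fixed penalty, and maps the segments to genomic domains.  Optionally
#' annotates each internal domain boundary with its maximum detecting
#' penalty (a reliability score; see [maxPenaltyScan()]) and classifies
#' domains with [classifyDomains()].
#'
#' @param track A \linkS4class{MethylomeTrack}.
#' @param penalty Fixed penalty per changepoint (default 1.0).
#' @param minDepth Coverage threshold (default 5 reads).
#' @param scanPenalty If TRUE, add a \code{maxPenalty} column: for each
#'   domain, the maximum grid penalty at which its LEFT boundary is
#'   detected (NA for the first domain of a chromosome, whose left edge is
#'   not a changepoint).
#' @param penaltyGrid Grid for the scan (see [defaultPenaltyGrid()]).
#' @param rules If non-NULL, label rules passed to [classifyDomains()].
#' @return A \linkS4class{GRanges} of domains.
#' @examples
#' sp <- simSpec(data.frame(chrom = "chr1", length = c(5e4, 5e4),
#'                          pi = c(0.9, 0.1)))
#' tr <- simulateMethylome(sp, seed = 1L)$track
#' callDomains(tr, penalty = 1, minDepth = 5)
#' @export
callDomains <- function(track, penalty = 1.0, minDepth = 5L,
                        scanPenalty = FALSE,
                        penaltyGrid = defaultPenaltyGrid(),
                        rules = NULL) {
    track <- filterByCoverage(track, minDepth)
    segs <- segmentTrack(track, penalty)
    dom <- buildDomains(track, segs)
    if (scanPenalty && length(dom)) {
        gr <- sites(track)
        lv <- methLevel(track)
        chr <- as.character(seqnames(gr))
        mp <- rep(NA_real_, length(dom))
        dchr <- as.character(seqnames(dom))
        for (cn in names(segs)) {
            scan <- maxPenaltyScan(lv[chr == cn], penaltyGrid)
            di <- which(dchr == cn)
            cp <- segs[[cn]]@changepoints        # left boundary of domains 2..k
            if (length(cp))
                mp[di[-1L]] <- unname(scan[as.character(cp)])
        }
        mcols(dom)$maxPenalty <- mp
    }
    if (!is.null(rules)) dom <- classifyDomains(dom, rules)
    dom
}

#' Default domain label rules
#'
#' Named predicates over (domain size in bp, mean methylation level).
#' \itemize{
#'   \item \code{PMD}: size > 10 kb and mean level < 0.70 (partially
#'     methylated domain).
#'   \item \code{DMV}: size > 5 kb and mean level < 0.15 (DNA methylation
#'     valley).
#'   \item \code{FMR}: size >= 1 kb and mean level >= 0.70 (highly
#'     methylated domains; sizes range up to Mb scale).
#'   \item \code{LMR}: 100 bp <= size <= 1.5 kb and 0.10 <= mean level
#'     < 0.50 (short low-to-moderately methylated domains).
#'   \item \code{UMR}: 1 kb <= size <= 3 kb and mean level < 0.10
#'     (unmethylated domains, typically CpG-island promoters).
#' }
#' PMD and DMV thresholds follow the published criteria for those
#' features; the FMR/LMR/UMR predicates are configurable numeric proxies
#' for the three major clusters seen in methylated domain landscapes.
#' Labels may co-occur.
#'
#' @return Named list of functions \code{f(size, meth)} returning logical.
#' @export
defaultLabelRules <- function() {
    list(
        PMD = function(size, meth) size > 10000 & meth < 0.70,
        DMV = function(size, meth) size > 5000 & meth < 0.15,
        FMR = function(size, meth) size >= 1000 & meth >= 0.70,
        LMR = function(size, meth) size >= 100 & size <= 1500 &
                                   meth >= 0.10 & meth < 0.50,
        UMR = function(size, meth) size >= 1000 & size <= 3000 &
                                   meth < 0.10)
}

#' Build label rules from a threshold list
#'
#' Converts a plain list of per-label numeric thresholds (as read from a
#' YAML/JSON configuration) into predicate functions usable by
#' [classifyDomains()].  Recognized keys per label: \code{min_size},
#' \code{max_size} (bp; \code{min_size} is strict when
#' \code{strict_min_size} is TRUE), \code{min_meth}, \code{max_meth}
#' (level; \code{max_meth} is exclusive).  Missing keys are unbounded.
#'
#' @param x Named list of lists, e.g.
#'   \code{list(PMD = list(min_size = 10000, max_meth = 0.70,
#'   strict_min_size = TRUE))}.
#' @return Named list of predicates for [classifyDomains()].
#' @export
labelRulesFromList <- function(x) {
    stopifnot(is.list(x), !is.null(names(x)))
    lapply(x, function(r) {
        force(r)
        function(size, meth) {
            ok <- rep(TRUE, length(size))
            if (!is.null(r$min_size))
                ok <- ok & (if (isTRUE(r$strict_min_size))
                                size > r$min_size else size >= r$min_size)
            if (!is.null(r$max_size)) ok <- ok & size <= r$max_size
            if (!is.null(r$min_meth)) ok <- ok & meth >= r$min_meth
            if (!is.null(r$max_meth)) ok <- ok & meth < r$max_meth
            ok
        }
    })
}

#' Classify domains by size and mean methylation level
#'
#' Evaluates each rule on every domain and records ALL labels whose
#' predicates hold (labels may co-occur, e.g. a large unmethylated domain
#' is both PMD- and DMV-like).
#'
#' @param domains A \linkS4class{GRanges} with a \code{meanMeth} column.
#' @param rules Named list of predicates \code{f(size, meth)}; default
#'   [defaultLabelRules()].
#' @return \code{domains} with a \code{labels} \linkS4class{CharacterList}
#'   metadata column.
#' @export
classifyDomains <- function(domains, rules = defaultLabelRules()) {
    stopifnot(is.list(rules), !is.null(names(rules)))
    size <- width(domains)
    meth <- mcols(domains)$meanMeth
    hit <- vapply(rules, function(f) as.logical(f(size, meth)),
                  logical(length(domains)))
    if (length(domains) == 1L) hit <- matrix(hit, nrow = 1L)
    labs <- apply(hit, 1L, function(h) names(rules)[which(h)],
                  simplify = FALSE)
    mcols(domains)$labels <- CharacterList(labs)
    domains
}

#' Fraction of each domain covered by a region set
#'
#' @param domains A \linkS4class{GRanges} of domains.
#' @param regions A \linkS4class{GRanges} reference region set (merged
#'   internally before computing coverage).
#' @return Numeric vector in [0, 1], one value per domain: covered bp /
#'   domain size.
#' @export
overlapFraction <- function(domains, regions) {
    red <- reduce(granges(regions), ignore.strand = TRUE)
    ov <- findOverlaps(domains, red, ignore.strand = TRUE)
    w <- width(pintersect(domains[queryHits(ov)], red[subjectHits(ov)],
                          ignore.strand = TRUE))
    covered <- numeric(length(domains))
    if (length(ov)) {
        agg <- rowsum(w, queryHits(ov))
        covered[as.integer(rownames(agg))] <- agg[, 1L]
    }
    covered / width(domains)
}

#' Select domains sufficiently covered by a region set
#'
#' Retains domains whose [overlapFraction()] with \code{regions} exceeds
#' \code{minFraction} (strictly; the default reproduces a "more than 80
#' percent overlap" selection).  Order is preserved.
#'
#' @inheritParams overlapFraction
#' @param minFraction Strict lower bound on the covered fraction.
#' @return Subset of \code{domains}.
#' @export
selectOverlapping <- function(domains, regions, minFraction = 0.8) {
    domains[overlapFraction(domains, regions) > minFraction]
}

#' Reciprocal base-pair coverage of two region sets
#'
#' @param a,b \linkS4class{GRanges} region sets (merged internally).
#' @return Named numeric vector \code{c(fracA, fracB)}: the fraction of
#'   the bases of \code{a} covered by \code{b}, and vice versa.
#' @export
regionCoverage <- function(a, b) {
    ra <- reduce(granges(a), ignore.strand = TRUE)
    rb <- reduce(granges(b), ignore.strand = TRUE)
    ib <- GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)
    wi <- sum(as.numeric(width(ib)))
    c(fracA = if (length(ra)) wi / sum(as.numeric(width(ra))) else 0,
      fracB = if (length(rb)) wi / sum(as.numeric(width(rb))) else 0)
}

#' Differentially methylated regions from two domain sets
#'
#' A minimal domain-based DMR caller: the two samples' domain sets are
#' intersected into atomic intervals (pieces covered by exactly one domain
#' in EACH sample), atoms whose per-sample mean levels differ by at least
#' \code{minLevelDiff} are flagged, and maximal runs of abutting flagged
#' atoms are merged into one reported DMR.  This captures both flavours of
#' domain-level difference: a shared domain with different levels, and a
#' boundary shift (where the non-shared piece becomes the DMR).  Run-level
#' means are recomputed as CpG-weighted means, each atom weighted by the
#' owning domain's CpG count prorated by overlap length.
#'
#' @param domainsA,domainsB Domain \linkS4class{GRanges} from the same
#'   genome build, with \code{nCpG} and \code{meanMeth} columns.
#' @param minLevelDiff Minimum absolute difference in mean methylation
#'   level (default 0.3).
#' @return A \linkS4class{GRanges} with columns \code{meanA},
#'   \code{meanB}, \code{diff}.
#' @export
detectDMRs <- function(domainsA, domainsB, minLevelDiff = 0.3) {
    stopifnot(minLevelDiff >= 0)
    empty <- GRanges()
    mcols(empty)$meanA <- numeric()
    mcols(empty)$meanB <- numeric()
    mcols(empty)$diff <- numeric()
    if (!length(domainsA) || !length(domainsB)) return(empty)

    atoms <- disjoin(c(granges(domainsA), granges(domainsB)),
                     ignore.strand = TRUE)
    ovA <- findOverlaps(atoms, domainsA, ignore.strand = TRUE)
    ovB <- findOverlaps(atoms, domainsB, ignore.strand = TRUE)
    ## domains within one sample are disjoint, so each atom hits <= 1 domain
    hitA <- rep(NA_integer_, length(atoms))
    hitA[queryHits(ovA)] <- subjectHits(ovA)
    hitB <- rep(NA_integer_, length(atoms))
    hitB[queryHits(ovB)] <- subjectHits(ovB)
    keep <- !is.na(hitA) & !is.na(hitB)
    if (!any(keep)) return(empty)
    atoms <- atoms[keep]; hitA <- hitA[keep]; hitB <- hitB[keep]

    mA <- mcols(domainsA)$meanMeth[hitA]
    mB <- mcols(domainsB)$meanMeth[hitB]
    flag <- abs(mA - mB) >= minLevelDiff
    if (!any(flag)) return(empty)
    fa <- atoms[flag]

    ## prorated CpG weight of an atom within its owning domain
    wA <- mcols(domainsA)$nCpG[hitA] * width(atoms) /
          width(domainsA)[hitA]
    wB <- mcols(domainsB)$nCpG[hitB] * width(atoms) /
          width(domainsB)[hitB]

    runs <- reduce(fa, ignore.strand = TRUE)   # merges abutting flagged atoms
    ovR <- findOverlaps(fa, runs, ignore.strand = TRUE)
    ri <- subjectHits(ovR)
    ai <- queryHits(ovR)
    fwA <- wA[flag][ai]; fwB <- wB[flag][ai]
    fmA <- mA[flag][ai]; fmB <- mB[flag][ai]
    meanA <- as.numeric(rowsum(fwA * fmA, ri) / rowsum(fwA, ri))
    meanB <- as.numeric(rowsum(fwB * fmB, ri) / rowsum(fwB, ri))
    mcols(runs)$meanA <- meanA
    mcols(runs)$meanB <- meanB
    mcols(runs)$diff <- meanA - meanB
    runs
}

#' Write DMRs as TSV
#'
#' Columns: chrom, start (0-based), end, meanA, meanB, diff.
#'
#' @param dmrs Result of [detectDMRs()].
#' @param path Output path.
#' @param meta '#' metadata header lines.
#' @return \code{path}, invisibly.
#' @export
writeDMRs <- function(dmrs, path, meta = character()) {
    df <- data.frame(chrom = as.character(seqnames(dmrs)),
                     start = start(dmrs) - 1L,
                     end = end(dmrs),
                     meanA = round(mcols(dmrs)$meanA, 6),
                     meanB = round(mcols(dmrs)$meanB, 6),
                     diff = round(mcols(dmrs)$diff, 6))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("#", meta), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
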