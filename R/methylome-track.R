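#' Construct a MethylomeTrack from per-site vectors
#'
#' Builds a \linkS4class{MethylomeTrack} from parallel vectors of
#' chromosome, position, methylated count and total coverage.  Sites with
#' zero coverage are dropped (their methylation level is undefined) and the
#' remaining sites are sorted by chromosome and position.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions of the C of each CpG on
#'   the plus strand.
#' @param M Integer vector of methylated read counts.
#' @param Cov Integer vector of total read counts.
#' @param sampleName Sample identifier.
#' @param minDepth Coverage threshold already applied (bookkeeping only;
#'   use [filterByCoverage()] to actually filter).
#' @return A \linkS4class{MethylomeTrack}.
#' @examples
#' tr <- MethylomeTrack(c("chr1", "chr1"), c(101L, 201L), c(3L, 0L),
#'                      c(6L, 8L), sampleName = "toy")
#' methLevel(tr)
#' @export
MethylomeTrack <- function(chrom, pos, M, Cov, sampleName = "sample",
                           minDepth = 1) {
    stopifnot(length(chrom) == length(pos),
              length(M) == length(pos),
              length(Cov) == length(pos))
    keep <- Cov > 0L
    gr <- GRanges(chrom[keep], IRanges(pos[keep], width = 1L))
    mcols(gr)$M <- as.integer(M[keep])
    mcols(gr)$Cov <- as.integer(Cov[keep])
    gr <- sort(gr, ignore.strand = TRUE)
    new("MethylomeTrack", sites = gr, sampleName = sampleName,
        minDepth = minDepth)
}

#' @rdname MethylomeTrack-class
#' @export
setMethod("sites", "MethylomeTrack", function(x) x@sites)

#' @rdname MethylomeTrack-class
#' @export
setMethod("sampleName", "MethylomeTrack", function(x) x@sampleName)

#' @rdname MethylomeTrack-class
#' @export
setMethod("length", "MethylomeTrack", function(x) length(x@sites))

#' @describeIn MethylomeTrack-class Per-site methylation level
#'   \code{M/Cov}, in the track's site order.
#' @export
setMethod("methLevel", "MethylomeTrack", function(x) {
    mc <- mcols(x@sites)
    as.numeric(mc$M) / as.numeric(mc$Cov)
})

setMethod("show", "MethylomeTrack", function(object) {
    gr <- object@sites
    cat("MethylomeTrack '", object@sampleName, "': ",
        length(gr), " CpG sites on ",
        length(seqlevelsInUse(gr)), " chromosome(s)",
        "; min depth ", object@minDepth, "\n", sep = "")
    if (length(gr)) {
        cov <- mcols(gr)$Cov
        cat("  mean coverage ", round(mean(cov), 2),
            ", mean level ", round(mean(methLevel(object)), 3), "\n",
            sep = "")
    }
})

#' Filter CpG sites by read coverage
#'
#' Retains only sites covered by at least \code{minDepth} reads.  Coverage
#' filtering is the single data-selection step applied before segmentation;
#' discarded sites take no part in any downstream computation.  The
#' operation is idempotent and monotone: raising \code{minDepth} never adds
#' a site back.
#'
#' @param x A \linkS4class{MethylomeTrack}.
#' @param minDepth Minimum total read count (default 5; typical choices
#'   are 3, 5 or 10 depending on sequencing depth).
#' @return A filtered \linkS4class{MethylomeTrack}.
#' @examples
#' tr <- MethylomeTrack("chr1", 101L, 3L, 4L)
#' length(filterByCoverage(tr, 5L))  # 0
#' @rdname filterByCoverage
#' @export
setMethod("filterByCoverage", "MethylomeTrack", function(x, minDepth = 5L) {
    stopifnot(length(minDepth) == 1L, minDepth >= 1)
    keep <- mcols(x@sites)$Cov >= minDepth
    new("MethylomeTrack", sites = x@sites[keep],
        sampleName = x@sampleName,
        minDepth = max(x@minDepth, minDepth))
})
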