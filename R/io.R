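## File formats
##
## bismark_report: TSV chrom, 1-based position, strand, count_methylated,
##   count_unmethylated, context, trinucleotide; only CpG/CG context rows
##   are used.  The two strands of one CpG are merged onto the plus-strand
##   C coordinate (minus-strand C sits one bp downstream).
## bedgraph_counts: TSV chrom, 0-based start, end, methylation percent,
##   count_methylated, count_unmethylated; already one row per CpG.
##
## All writers accept '#'-prefixed metadata header lines; all readers skip
## them.

.freadSafe <- function(path, ...) {
    con <- file(path, "r")
    skip <- 0L
    hasData <- FALSE
    repeat {
        ln <- readLines(con, n = 1L)
        if (!length(ln)) break
        if (startsWith(ln, "#")) { skip <- skip + 1L } else {
            hasData <- nzchar(trimws(ln))
            break
        }
    }
    close(con)
    if (!hasData) return(data.table::data.table())
    data.table::fread(path, header = FALSE, sep = "\t", skip = skip,
                      blank.lines.skip = TRUE, fill = TRUE,
                      data.table = TRUE, ...)
}

#' Read per-CpG methylation calls
#'
#' Reads a base-resolution methylome file into a
#' \linkS4class{MethylomeTrack}.  Two dialects are supported: the Bismark
#' CpG cytosine report (\code{"bismark_report"}: chrom, 1-based position,
#' strand, methylated count, unmethylated count, context, trinucleotide)
#' and a bedGraph-with-counts format (\code{"bedgraph_counts"}: chrom,
#' 0-based start, end, percent methylation, methylated count, unmethylated
#' count).  In the Bismark dialect the counts of the two Cs of one CpG are
#' summed onto the plus-strand C coordinate, so each CpG becomes a single
#' site.  Sites with zero total coverage are dropped at read time.
#'
#' @param path Path to the methylome file ('#' header lines are skipped).
#' @param dialect One of \code{"bismark_report"}, \code{"bedgraph_counts"}.
#' @param sampleName Sample identifier (defaults to the file name).
#' @return A \linkS4class{MethylomeTrack}.
#' @seealso [writeMethylome()], [filterByCoverage()]
#' @export
readMethylome <- function(path,
                          dialect = c("bismark_report", "bedgraph_counts"),
                          sampleName = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(sampleName))
        sampleName <- sub("\\.[^.]*$", "", basename(path))
    dt <- .freadSafe(path)
    if (nrow(dt) == 0L)
        return(MethylomeTrack(character(), integer(), integer(), integer(),
                              sampleName = sampleName))
    if (dialect == "bismark_report") {
        if (ncol(dt) < 5L)
            stop("bismark_report needs >= 5 columns, found ", ncol(dt))
        chrom <- as.character(dt[[1L]])
        pos1 <- suppressWarnings(as.integer(dt[[2L]]))
        strand <- as.character(dt[[3L]])
        m <- suppressWarnings(as.integer(dt[[4L]]))
        u <- suppressWarnings(as.integer(dt[[5L]]))
        bad <- which(is.na(pos1) | is.na(m) | is.na(u) |
                     !(strand %in% c("+", "-")))
        if (length(bad))
            stop("malformed bismark_report record at data line ", bad[1L],
                 " of ", path)
        if (ncol(dt) >= 6L) {
            ctx <- as.character(dt[[6L]])
            keep <- ctx %in% c("CpG", "CG")
            chrom <- chrom[keep]; pos1 <- pos1[keep]
            strand <- strand[keep]; m <- m[keep]; u <- u[keep]
        }
        ## plus-strand C coordinate of the CpG unit
        posC <- ifelse(strand == "+", pos1, pos1 - 1L)
        if (anyDuplicated(paste(chrom, posC, strand)))
            stop("duplicate site (same chrom, position, strand) in ", path)
        key <- paste(chrom, posC)
        M <- rowsum(m, key, reorder = FALSE)
        Cov <- rowsum(m + u, key, reorder = FALSE)
        first <- !duplicated(key)
        MethylomeTrack(chrom[first], posC[first],
                       as.integer(M[, 1L]), as.integer(Cov[, 1L]),
                       sampleName = sampleName)
    } else {
        if (ncol(dt) < 6L)
            stop("bedgraph_counts needs 6 columns, found ", ncol(dt))
        chrom <- as.character(dt[[1L]])
        start0 <- suppressWarnings(as.integer(dt[[2L]]))
        m <- suppressWarnings(as.integer(dt[[5L]]))
        u <- suppressWarnings(as.integer(dt[[6L]]))
        bad <- which(is.na(start0) | is.na(m) | is.na(u))
        if (length(bad))
            stop("malformed bedgraph_counts record at data line ", bad[1L],
                 " of ", path)
        if (anyDuplicated(paste(chrom, start0)))
            stop("duplicate position in ", path)
        MethylomeTrack(chrom, start0 + 1L, m, m + u,
                       sampleName = sampleName)
    }
}

#' Write a MethylomeTrack to file
#'
#' @param x A \linkS4class{MethylomeTrack}.
#' @param path Output path.
#' @param dialect Output format; see [readMethylome()].  Bismark output is
#'   written as one merged plus-strand row per CpG.
#' @param meta Character vector of metadata lines to embed as '#' headers.
#' @return \code{path}, invisibly.
#' @export
writeMethylome <- function(x, path,
                           dialect = c("bedgraph_counts", "bismark_report"),
                           meta = character()) {
    dialect <- match.arg(dialect)
    gr <- sites(x)
    m <- mcols(gr)$M
    cov <- mcols(gr)$Cov
    chrom <- as.character(seqnames(gr))
    pos1 <- start(gr)
    df <- if (dialect == "bedgraph_counts") {
        data.frame(chrom = chrom, start = pos1 - 1L, end = pos1 + 1L,
                   pct = round(ifelse(cov > 0, 100 * m / cov, 0), 6),
                   M = m, U = cov - m)
    } else {
        data.frame(chrom = chrom, pos = pos1, strand = "+",
                   M = m, U = cov - m, context = "CpG", tri = "CGN")
    }
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("#", meta), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a reference region set (BED3/BED4)
#'
#' Imports a BED file of reference intervals (for instance externally
#' defined UMR/LMR/FMR/PMD/DMV calls) and normalizes it: intervals sharing
#' a label are merged where they overlap or abut; intervals with different
#' labels are kept separate.  Unnamed intervals get the label \code{"."}.
#'
#' @param path Path to a BED3 or BED4 file (0-based half-open).
#' @return A sorted \linkS4class{GRanges} with a \code{label} metadata
#'   column, non-overlapping within each label.
#' @export
readRegionSet <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) && any(width(gr) < 1L))
        stop("region with start >= end in ", path)
    lab <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
           else rep(".", length(gr))
    lab[is.na(lab)] <- "."
    parts <- lapply(split(granges(gr), lab), reduce)
    out <- GRanges()
    for (l in names(parts)) {
        p <- parts[[l]]
        mcols(p)$label <- rep(l, length(p))
        out <- c(out, p)
    }
    sort(out, ignore.strand = TRUE)
}

#' Write a domain set as BED6-like TSV
#'
#' Columns: chrom, start (0-based), end, name (comma-joined labels or
#' \code{"."}), score (mean methylation x 1000, integer), strand
#' (\code{"."}), then extended columns nCpG, meanMeth and maxPenalty.
#'
#' @param domains A \linkS4class{GRanges} of domains as returned by
#'   [buildDomains()] or [callDomains()].
#' @param path Output path.
#' @param meta Character vector of metadata lines embedded as '#' headers.
#' @return \code{path}, invisibly.
#' @export
writeDomains <- function(domains, path, meta = character()) {
    mc <- mcols(domains)
    lab <- if (!is.null(mc$labels)) {
        v <- vapply(mc$labels, function(l) paste(l, collapse = ","),
                    character(1))
        ifelse(nzchar(v), v, ".")
    } else rep(".", length(domains))
    mp <- if (!is.null(mc$maxPenalty)) mc$maxPenalty
          else rep(NA_real_, length(domains))
    df <- data.frame(chrom = as.character(seqnames(domains)),
                     start = start(domains) - 1L,
                     end = end(domains),
                     name = lab,
                     score = as.integer(round(mc$meanMeth * 1000)),
                     strand = ".",
                     nCpG = mc$nCpG,
                     meanMeth = round(mc$meanMeth, 6),
                     maxPenalty = mp)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("#", meta), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a domain file written by [writeDomains()]
#'
#' @param path Path to a domain TSV ('#' headers skipped).
#' @return A \linkS4class{GRanges} with metadata columns \code{nCpG},
#'   \code{meanMeth}, \code{maxPenalty} and \code{labels}.
#' @export
readDomains <- function(path) {
    dt <- .freadSafe(path)
    if (nrow(dt) == 0L) return(GRanges())
    if (ncol(dt) < 9L)
        stop("domain file needs 9 columns, found ", ncol(dt))
    gr <- GRanges(as.character(dt[[1L]]),
                  IRanges(as.integer(dt[[2L]]) + 1L, as.integer(dt[[3L]])))
    mcols(gr)$nCpG <- as.integer(dt[[7L]])
    mcols(gr)$meanMeth <- as.numeric(dt[[8L]])
    mcols(gr)$maxPenalty <- suppressWarnings(as.numeric(dt[[9L]]))
    nm <- as.character(dt[[4L]])
    mcols(gr)$labels <- CharacterList(
        lapply(nm, function(s) if (s == ".") character() else
                   strsplit(s, ",", fixed = TRUE)[[1L]]))
    gr
}
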