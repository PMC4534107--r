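## Methylated Domain Landscape (MDL): a fixed 20 x 20 histogram of domains
## over (log10 size, mean methylation level).  The grid is identical across
## samples so that pixel vectors are directly comparable.

#' Compute a Methylated Domain Landscape matrix
#'
#' Bins every domain by log10(size in bp) on the horizontal axis and by
#' mean methylation level on the vertical axis into a fixed grid (default
#' 20 x 20 = 400 pixels spanning [100 bp, 1e7 bp] x [0, 1]).  Bins are
#' half-open [low, high) with the final bin closed.  Domains outside the
#' grid are counted in \code{outOfRange} rather than dropped, so counts
#' are conserved; they are excluded from clustering vectors.
#'
#' @param domains A \linkS4class{GRanges} with a \code{meanMeth} column;
#'   all widths must be >= 1 bp.
#' @param sizeRange Size axis bounds in bp (geometric bins), default
#'   \code{c(100, 1e7)}: wide enough to span everything from sub-kb
#'   low-methylated domains to Mb-scale fully methylated ones.
#' @param methRange Methylation axis bounds, default \code{c(0, 1)}.
#' @param bins Number of bins per axis (default 20).
#' @param sampleName Sample identifier stored in the result.
#' @return An \linkS4class{MDLMatrix}.
#' @examples
#' d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' GenomicRanges::mcols(d)$meanMeth <- 0.85
#' computeMDL(d)
#' @export
computeMDL <- function(domains, sizeRange = c(100, 1e7),
                       methRange = c(0, 1), bins = 20L,
                       sampleName = "sample") {
    stopifnot(length(sizeRange) == 2L, sizeRange[1] > 0,
              sizeRange[1] < sizeRange[2],
              length(methRange) == 2L, methRange[1] < methRange[2],
              bins >= 1L)
    size <- width(domains)
    if (length(size) && any(size < 1L)) stop("domain with non-positive size")
    meth <- mcols(domains)$meanMeth
    if (is.null(meth)) {
        if (length(domains)) stop("domains need a 'meanMeth' column")
        meth <- numeric(0)
    }
    sizeEdges <- 10^seq(log10(sizeRange[1]), log10(sizeRange[2]),
                        length.out = bins + 1L)
    methEdges <- seq(methRange[1], methRange[2], length.out = bins + 1L)
    si <- findInterval(log10(size), log10(sizeEdges),
                       rightmost.closed = TRUE)
    mi <- findInterval(meth, methEdges, rightmost.closed = TRUE)
    inb <- si >= 1L & si <= bins & mi >= 1L & mi <= bins
    counts <- matrix(0L, nrow = bins, ncol = bins)
    if (any(inb)) {
        tab <- table(factor(mi[inb], levels = seq_len(bins)),
                     factor(si[inb], levels = seq_len(bins)))
        counts <- matrix(as.integer(tab), nrow = bins, ncol = bins)
    }
    new("MDLMatrix", counts = counts, sizeEdges = sizeEdges,
        methEdges = methEdges, total = sum(counts),
        outOfRange = sum(!inb), sampleName = sampleName)
}

#' @rdname MDLMatrix-class
#' @param object,x An \linkS4class{MDLMatrix}.
#' @export
mdlCounts <- function(x) x@counts

setMethod("show", "MDLMatrix", function(object) {
    cat("MDLMatrix '", object@sampleName, "': ",
        nrow(object@counts), " x ", ncol(object@counts), " grid, ",
        object@total, " domains binned, ",
        object@outOfRange, " out of range\n", sep = "")
    cat("  size ", format(object@sizeEdges[1L], digits = 3), "-",
        format(object@sizeEdges[length(object@sizeEdges)], digits = 3),
        " bp (log10 bins), meth ", object@methEdges[1L], "-",
        object@methEdges[length(object@methEdges)], "\n", sep = "")
})

#' Flatten an MDL matrix to its pixel vector
#'
#' Deterministic row-major flattening (methylation bin varies slowest):
#' the 400-element vector used for Spearman comparison and clustering.
#'
#' @param x An \linkS4class{MDLMatrix}.
#' @return Integer vector of length \code{bins^2}.
#' @rdname mdlVector
#' @export
setMethod("mdlVector", "MDLMatrix", function(x) {
    as.integer(t(x@counts))
})

.sameGrid <- function(a, b) {
    isTRUE(all.equal(a@sizeEdges, b@sizeEdges)) &&
        isTRUE(all.equal(a@methEdges, b@methEdges))
}

#' Write / read an MDL matrix as TSV
#'
#' The file carries '#' header lines with the bin edges followed by the
#' integer count grid (rows = methylation bins, low to high).
#'
#' @param x An \linkS4class{MDLMatrix}.
#' @param path File path.
#' @param meta Extra '#' metadata lines.
#' @return \code{path} (writer) or an \linkS4class{MDLMatrix} (reader).
#' @export
writeMDLMatrix <- function(x, path, meta = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("#", meta), con)
    writeLines(c(paste0("#sample=", x@sampleName),
                 paste0("#size_edges=", paste(format(x@sizeEdges, digits = 15),
                                              collapse = ",")),
                 paste0("#meth_edges=", paste(format(x@methEdges, digits = 15),
                                              collapse = ",")),
                 paste0("#out_of_range=", x@outOfRange)), con)
    utils::write.table(x@counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeMDLMatrix
#' @export
readMDLMatrix <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    getfield <- function(key) {
        ln <- grep(paste0("^#", key, "="), hdr, value = TRUE)
        if (!length(ln)) stop("missing '", key, "' header in ", path)
        sub(paste0("^#", key, "="), "", ln[1L])
    }
    sizeEdges <- as.numeric(strsplit(getfield("size_edges"), ",")[[1L]])
    methEdges <- as.numeric(strsplit(getfield("meth_edges"), ",")[[1L]])
    oor <- as.integer(getfield("out_of_range"))
    sn <- tryCatch(getfield("sample"), error = function(e) "sample")
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(trimws(body))]
    counts <- do.call(rbind, lapply(strsplit(body, "\t"), as.integer))
    new("MDLMatrix", counts = counts, sizeEdges = sizeEdges,
        methEdges = methEdges, total = sum(counts),
        outOfRange = oor, sampleName = sn)
}

#' Render an MDL matrix as a PNG raster
#'
#' Pseudocolor density image (log-scaled counts, white through blue to
#' red), size on the horizontal axis increasing rightward and methylation
#' level on the vertical axis increasing upward.  Purely presentational.
#'
#' @param x An \linkS4class{MDLMatrix}.
#' @param path Output PNG path.
#' @param pixelSize Edge length in image pixels per grid cell.
#' @return \code{path}, invisibly.
#' @export
renderMDL <- function(x, path, pixelSize = 12L) {
    cnt <- x@counts
    z <- log1p(cnt)
    zmax <- max(z, 1e-9)
    ramp <- grDevices::colorRamp(c("white", "steelblue", "yellow", "red"))
    rgbv <- ramp(as.vector(z / zmax)) / 255
    nb <- nrow(cnt)
    img <- array(0, dim = c(nb, ncol(cnt), 3L))
    for (k in 1:3)
        img[, , k] <- matrix(rgbv[, k], nrow = nb)
    img <- img[rev(seq_len(nb)), , , drop = FALSE]  # meth increases upward
    big <- img[rep(seq_len(nb), each = pixelSize),
               rep(seq_len(ncol(cnt)), each = pixelSize), , drop = FALSE]
    png::writePNG(big, target = path)
    invisible(path)
}
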