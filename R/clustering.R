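## MDL-based methylome comparison: Spearman rank correlation of pixel
## vectors, Ward clustering of 1 - rho.

#' Spearman similarity matrix of MDL pixel vectors
#'
#' Computes pairwise Spearman rank-order correlation between samples'
#' MDL pixel vectors.  Ties (typically the many pixels with zero counts)
#' receive average ranks, the standard Spearman convention.
#'
#' @param x Either a named list of \linkS4class{MDLMatrix} objects on the
#'   identical grid, or a numeric matrix with one column per sample
#'   (rows = pixels).
#' @return Symmetric numeric matrix of Spearman rho with unit diagonal and
#'   sample names as dimnames.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 0), b = c(0, 3, 2, 1))
#' spearmanMatrix(m)
#' @export
spearmanMatrix <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
        if (length(x) < 2L) stop("need at least two samples")
        if (is.null(names(x)))
            names(x) <- paste0("sample", seq_along(x))
        for (i in seq_along(x)[-1L])
            if (!.sameGrid(x[[1L]], x[[i]]))
                stop("MDL grids differ between samples '",
                     names(x)[1L], "' and '", names(x)[i], "'")
        x <- vapply(x, mdlVector, integer(length(mdlVector(x[[1L]]))))
    }
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("need at least two samples")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("sample", seq_len(ncol(x)))
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance pixel vector for sample '",
             colnames(x)[which(sds == 0)[1L]], "'")
    rho <- stats::cor(x, method = "spearman")
    diag(rho) <- 1
    rho
}

#' Ward clustering of a similarity matrix
#'
#' Converts the Spearman similarity to the dissimilarity \code{1 - rho}
#' and applies Ward's minimum-variance linkage to the precomputed distance
#' matrix.  Leaf order and merge heights are deterministic given the
#' input; relabeling the samples permutes leaves but leaves heights
#' unchanged.
#'
#' @param similarity Symmetric similarity matrix (unit diagonal) as
#'   returned by [spearmanMatrix()].
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default \code{"ward.D2"}).
#' @return An \code{hclust} object.
#' @seealso [asNewick()] to serialize the dendrogram.
#' @export
wardCluster <- function(similarity, method = "ward.D2") {
    similarity <- as.matrix(similarity)
    if (nrow(similarity) < 2L) stop("need at least two samples")
    if (max(abs(similarity - t(similarity))) > 1e-8)
        stop("similarity matrix must be symmetric")
    d <- stats::as.dist(1 - similarity)
    stats::hclust(d, method = method)
}

#' Serialize a dendrogram as a Newick string
#'
#' @param hc An \code{hclust} object from [wardCluster()].
#' @param path Optional file to write the tree to.
#' @return The Newick string, invisibly when written to file.
#' @export
asNewick <- function(hc, path = NULL) {
    phy <- ape::as.phylo(hc)
    if (is.null(path)) {
        ape::write.tree(phy)
    } else {
        ape::write.tree(phy, file = path)
        invisible(ape::write.tree(phy))
    }
}

#' Write a similarity matrix as TSV
#'
#' @param similarity Matrix from [spearmanMatrix()].
#' @param path Output path.
#' @param meta '#' metadata header lines.
#' @return \code{path}, invisibly.
#' @export
writeSimilarity <- function(similarity, path, meta = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("#", meta), con)
    df <- data.frame(sample = rownames(similarity),
                     round(as.data.frame(similarity), 6),
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Render a similarity heatmap ordered by the dendrogram
#'
#' Writes a pseudocolor PNG of the similarity matrix with rows and columns
#' ordered by the Ward dendrogram leaf order, the standard companion view
#' of the clustering.  Purely presentational.
#'
#' @param similarity Matrix from [spearmanMatrix()].
#' @param path Output PNG path.
#' @param hc Optional precomputed \code{hclust}; computed with
#'   [wardCluster()] if missing.
#' @param pixelSize Image pixels per matrix cell.
#' @return \code{path}, invisibly.
#' @export
renderSimilarityHeatmap <- function(similarity, path, hc = NULL,
                                    pixelSize = 24L) {
    if (is.null(hc)) hc <- wardCluster(similarity)
    ord <- hc$order
    m <- similarity[ord, ord, drop = FALSE]
    z <- (m - min(m)) / max(max(m) - min(m), 1e-12)
    ramp <- grDevices::colorRamp(c("white", "red"))
    rgbv <- ramp(as.vector(z)) / 255
    n <- nrow(m)
    img <- array(0, dim = c(n, n, 3L))
    for (k in 1:3) img[, , k] <- matrix(rgbv[, k], nrow = n)
    big <- img[rep(seq_len(n), each = pixelSize),
               rep(seq_len(n), each = pixelSize), , drop = FALSE]
    png::writePNG(big, target = path)
    invisible(path)
}
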