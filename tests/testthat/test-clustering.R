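## Archetype domain generators: two populations with distinct MDL shapes.
archetypeDomains <- function(kind, n = 2000L) {
    if (kind == "somatic") {                 # many large, highly methylated
        size <- round(10^rnorm(n, 4.5, 0.6))
        meth <- pmin(1, pmax(0, rnorm(n, 0.85, 0.08)))
    } else {                                 # many small, lowly methylated
        size <- round(10^rnorm(n, 3.0, 0.5))
        meth <- pmin(1, pmax(0, rnorm(n, 0.25, 0.12)))
    }
    gr <- GRanges("chr1", IRanges(1, width = pmax(size, 10)))
    mcols(gr)$meanMeth <- meth
    gr
}

test_that("Spearman similarity obeys its defining identities", {
    v <- c(5, 1, 4, 2, 8, 0, 0, 3)
    ## self-correlation 1; exact rank reversal -1
    rho <- spearmanMatrix(cbind(a = v, b = -v))
    expect_equal(rho["a", "b"], -1)
    expect_equal(diag(rho), c(a = 1, b = 1))
    expect_equal(spearmanMatrix(cbind(a = v, b = v))["a", "b"], 1)
})

test_that("tie-heavy vectors match the rank-then-Pearson oracle", {
    set.seed(61)
    for (i in 1:10) {
        x <- rpois(400, 0.7)                 # many zeros, like MDL pixels
        y <- rpois(400, 0.7) + rbinom(400, 1, 0.2) * x
        got <- spearmanMatrix(cbind(a = x, b = y))["a", "b"]
        want <- cor(rank(x), rank(y))        # average ranks for ties
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("degenerate inputs are rejected with the offending sample named", {
    expect_error(spearmanMatrix(cbind(a = c(1, 2), b = c(3, 3))), "b")
    expect_error(spearmanMatrix(matrix(1:4, ncol = 1)), "two samples")
    set.seed(63)
    m1 <- computeMDL(archetypeDomains("somatic"), sampleName = "s1")
    m2 <- computeMDL(archetypeDomains("somatic"), sizeRange = c(10, 1e6),
                     sampleName = "s2")
    expect_error(spearmanMatrix(list(s1 = m1, s2 = m2)), "grids differ")
})

test_that("two samples merge once at a height set by their distance", {
    set.seed(65)
    a <- computeMDL(archetypeDomains("somatic"), sampleName = "a")
    b <- computeMDL(archetypeDomains("escLike"), sampleName = "b")
    rho <- spearmanMatrix(list(a = a, b = b))
    hc <- wardCluster(rho)
    expect_equal(length(hc$height), 1L)
    expect_equal(hc$height, as.numeric(1 - rho["a", "b"]), tolerance = 1e-9)
})

test_that("a duplicated sample merges first at height zero", {
    set.seed(67)
    mdls <- list(x = computeMDL(archetypeDomains("somatic"),
                                sampleName = "x"),
                 y = computeMDL(archetypeDomains("escLike"),
                                sampleName = "y"))
    mdls$x2 <- mdls$x
    rho <- spearmanMatrix(mdls)
    hc <- wardCluster(rho)
    expect_equal(min(hc$height), 0)
    first <- sort(abs(hc$merge[1L, ]))
    expect_equal(rownames(rho)[first], c("x", "x2"))
})

test_that("designed archetype groups are recovered as the top bipartition", {
    set.seed(69)
    mdls <- c(lapply(1:2, function(i) computeMDL(archetypeDomains("somatic"),
                                                 sampleName = paste0("g1_", i))),
              lapply(1:3, function(i) computeMDL(archetypeDomains("escLike"),
                                                 sampleName = paste0("g2_", i))))
    names(mdls) <- c("g1_1", "g1_2", "g2_1", "g2_2", "g2_3")
    rho <- spearmanMatrix(mdls)
    hc <- wardCluster(rho)
    grp <- stats::cutree(hc, k = 2)
    expect_equal(length(unique(grp[1:2])), 1L)
    expect_equal(length(unique(grp[3:5])), 1L)
    expect_true(grp[1] != grp[3])
})

test_that("relabeling samples permutes leaves but not merge heights", {
    set.seed(71)
    mdls <- list(a = computeMDL(archetypeDomains("somatic"), sampleName = "a"),
                 b = computeMDL(archetypeDomains("escLike"), sampleName = "b"),
                 c = computeMDL(archetypeDomains("somatic"), sampleName = "c"),
                 d = computeMDL(archetypeDomains("escLike"), sampleName = "d"))
    rho <- spearmanMatrix(mdls)
    perm <- c(3L, 1L, 4L, 2L)
    rhoP <- rho[perm, perm]
    expect_equal(sort(wardCluster(rho)$height),
                 sort(wardCluster(rhoP)$height), tolerance = 1e-12)
})

test_that("dendrograms serialize to Newick with heights as branch lengths", {
    set.seed(73)
    mdls <- list(a = computeMDL(archetypeDomains("somatic"), sampleName = "a"),
                 b = computeMDL(archetypeDomains("escLike"), sampleName = "b"),
                 c = computeMDL(archetypeDomains("somatic"), sampleName = "c"))
    rho <- spearmanMatrix(mdls)
    hc <- wardCluster(rho)
    nwk <- asNewick(hc)
    phy <- ape::read.tree(text = nwk)
    expect_setequal(phy$tip.label, c("a", "b", "c"))
    p <- tempfile(fileext = ".nwk")
    asNewick(hc, p)
    expect_equal(ape::read.tree(p)$tip.label, phy$tip.label)
})

test_that("similarity TSV and heatmap outputs are written", {
    set.seed(75)
    mdls <- list(a = computeMDL(archetypeDomains("somatic"), sampleName = "a"),
                 b = computeMDL(archetypeDomains("escLike"), sampleName = "b"))
    rho <- spearmanMatrix(mdls)
    p1 <- tempfile(fileext = ".tsv")
    writeSimilarity(rho, p1, meta = "n=2")
    lines <- readLines(p1)
    expect_true(startsWith(lines[1], "#"))
    expect_match(lines[2], "^sample\t")
    p2 <- tempfile(fileext = ".png")
    renderSimilarityHeatmap(rho, p2)
    expect_gt(file.size(p2), 0)
})
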