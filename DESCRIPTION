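Package: MethylScape
Title: Methylome Segmentation by Penalized Changepoint Detection and
    Methylated Domain Landscapes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments base-resolution whole-genome bisulfite sequencing
    (WGBS) methylomes into methylated domains using exact penalized
    least-squares changepoint detection (PELT) with a fixed, data-size
    independent penalty. Each methylome is summarised as a Methylated
    Domain Landscape (MDL): a 20 x 20 count matrix of domains over
    (log10 size, mean methylation level). MDL pixel vectors are compared
    by Spearman rank correlation and clustered with Ward's method,
    providing a compact signature of each methylome. Includes domain
    classification (PMD/DMV/FMR/LMR/UMR-like), overlap analysis against
    reference region sets, simple domain-based DMR calling, read-count
    thinning for data-size robustness experiments, and a seeded synthetic
    methylome generator with known domain structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    ape,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, Sequencing, Clustering,
    WholeGenome
RoxygenNote: 7.3.3
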