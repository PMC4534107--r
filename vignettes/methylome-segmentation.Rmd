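---
title: "Methylome segmentation and domain landscapes with MethylScape"
author: "MethylScape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome segmentation and domain landscapes with MethylScape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylScape)
```

## The model

Whole-genome bisulfite sequencing (WGBS) reports, for every CpG site, the
number of methylated and total read calls.  Most CpGs are not regulated
independently: they form *methylated domains* — runs of consecutive sites
sharing a common methylation level.  MethylScape treats each chromosome's
methylation levels $X_1, \dots, X_N$ (one value per retained CpG, in CpG
order) as a piecewise-constant-mean series and finds the domain boundaries
by exact penalized least-squares changepoint detection.

The cost of a candidate segment spanning sites $k$ through $n$ is the
within-segment sum of squares

$$C(k{:}n) = \sum_{i=k}^{n} (X_i - \mu)^2,$$

with $\mu$ the segment mean, and a segmentation with changepoints
$t_1 < \dots < t_m$ is scored by $\sum_j C_j + \beta m$.  A boundary at
$t$ is therefore introduced only when
$C(1{:}N) > C(1{:}t) + C(t{+}1{:}N) + \beta$: the penalty $\beta$ is the
single tuning parameter of the whole method.  The optimum is computed by
the PELT recursion (`peltSegment()`), which prunes candidate split points
but is guaranteed to return the same objective as exhaustive dynamic
programming; the unpruned $O(N^2)$ recursion is kept as `dpSegment()` and
the two are cross-checked exactly in the test suite.

Two modelling commitments are deliberate:

* **The penalty is a fixed constant, independent of data size.**  Scaling
  $\beta$ with $N$ (as information criteria do) would make detection
  sensitivity differ between a 50-Mb and a 250-Mb chromosome.  A fixed
  $\beta$ keeps the meaning of a boundary identical genome-wide.  The
  default $\beta = 1.0$ balances sensitivity and specificity for
  methylation levels, which live in $[0,1]$: lowering it recovers small
  CpG-island-scale features, raising it merges over-segmented large
  domains.
* **Genomic distance between CpGs is ignored.**  CpGs are irregularly
  spaced and no objective distance model presents itself; the series
  index is simply the CpG ordinal.  Chromosomes are segmented
  independently, so a boundary can never span a chromosome end.

### Boundary reliability

Because sensitivity is controlled by a single number, re-running the
segmentation over a penalty grid gives a natural per-boundary reliability
score: the largest penalty at which a boundary is still detected
(`maxPenaltyScan()`).  The default grid is geometric, 25 points from 0.05
to 50 — wide enough that the weakest boundaries fall off near the bottom
and only the strongest survive the top.  The grid is a configurable
stand-in for the exact penalty path; reported values are always grid
members.

## From changepoints to domains

Changepoints live in CpG-ordinal space; `buildDomains()` maps them back
to the genome.  A domain runs from its first CpG position to its last CpG
position plus one, covering the terminal CpG dinucleotide — the genomic
extent of a run of CpGs has no canonical definition, and this convention
makes every single-CpG domain 2 bp wide and domain size equal `end -
start` in BED space.  Intervals before the first and after the last CpG
of a chromosome carry no data and receive no domain.  Per domain we
report the CpG count and the arithmetic mean of member site levels;
domains partition the retained CpGs exactly, a conservation law the tests
assert on every randomized instance.

Domains are classified by configurable predicates over (size, mean
level); `defaultLabelRules()` provides PMD-like (> 10 kb, level < 0.70)
and DMV-like (> 5 kb, level < 0.15) rules following the published
criteria for those features, plus FMR/LMR/UMR-like proxies for the three
clusters that dominate domain landscapes (highly methylated kb-to-Mb
domains; short low-to-moderate domains of 100 bp–1.5 kb; unmethylated
1–3 kb domains).  The cluster predicates are descriptive conveniences,
not claims: adjust them to your organism and question via
`labelRulesFromList()`.  Overlap against externally defined region sets
uses strict base-pair arithmetic (`overlapFraction()`,
`regionCoverage()`), and `selectOverlapping()` keeps domains whose
covered fraction strictly exceeds the cutoff (default 0.8).

A minimal domain-based DMR caller is included (`detectDMRs()`): the two
domain sets are atomized by intersection, atoms whose per-sample means
differ by at least 0.3 (configurable) are flagged, and maximal runs of
abutting flagged atoms are reported with CpG-weighted run means.  Atom
weights prorate each domain's CpG count by overlap length, since the
caller sees only domains, not the original tracks.  No significance
testing is attempted — this is boundary arithmetic, not inference.

## The Methylated Domain Landscape

`computeMDL()` summarises a methylome as a fixed 20 × 20 histogram of its
domains over ($\log_{10}$ size, mean level) — 400 pixels.  The default
axis ranges $[100\,\mathrm{bp}, 10^7\,\mathrm{bp}] \times [0, 1]$ span
everything from sub-kb regulatory features to Mb-scale partially
methylated domains, and are fixed across samples so pixel vectors are
comparable.  Bins are half-open with the last bin closed; domains outside
the grid are tallied in `outOfRange` rather than dropped (conservation
again: binned + out-of-range = input), and excluded from clustering
vectors.  `mdlVector()` flattens row-major (methylation bin slowest).

Methylomes are compared by Spearman rank correlation of their pixel
vectors — rank-based because pixel counts are heavily tied at zero and
span orders of magnitude — with average ranks for ties, and clustered by
Ward's method on the dissimilarity $d = 1 - \rho$
(`spearmanMatrix()`, `wardCluster()`).  Pairing Ward with a rank
correlation requires the "Ward on a precomputed dissimilarity"
convention; we use `stats::hclust(method = "ward.D2")`, the Ward variant
that treats the supplied dissimilarities as distances.  Dendrograms
serialize to Newick via `ape`.

## Data-size robustness and thinning

`thinCounts()` emulates a smaller sequencing run by retaining each read
independently with probability $f$, implemented at the count level: new
totals are $\mathrm{Binomial}(\mathrm{Cov}, f)$ and new methylated counts
hypergeometric, which is distributionally identical to per-read Bernoulli
retention (raw reads are out of scope).  Thinning is unbiased for the
methylation level.  In the robustness experiment the downsized datasets
are *nested* — each smaller dataset is a further thinning of the larger
one — emulating titration of a single run; binomial thinning composes,
so the nested 10 % set has exactly the distribution of a direct 10 %
thin.  On synthetic genomes the mean domain count rises with $f$ and
approaches a plateau: going from 10 % to 25 % of the data adds several
percent more domains, while going from 50 % to 100 % adds a fraction of
a percent.

## The synthetic generator

`simSpec()`/`simulateMethylome()` realize exactly the model the
segmentation assumes, plus the data features that matter for it:

* domains laid end-to-end with true levels $\pi$; per-site coverage
  Poisson (default mean 30, deep WGBS), methylated counts
  $\mathrm{Binomial}(\mathrm{Cov}, \pi)$; zero-coverage sites dropped as
  in real data;
* geometric inter-CpG gaps (mean 100 bp, a typical genome-wide spacing;
  minimum 2 bp so CpGs never overlap), with an optional ten-fold density
  increase inside designated "island" domains — this reproduces the
  practically important asymmetry that CpG-dense unmethylated regions
  perturb the cost function strongly and survive high penalties, while
  CpG-poor low-methylated regions vanish early.

What the generator does **not** emulate: bisulfite conversion errors,
mapping bias, biological replicate variance, non-CpG methylation,
gradual methylation slopes (the model is piecewise constant by
construction; a real gradient will be approximated by stair-steps), and
correlated coverage along the genome.  Tests passing on synthetic data
therefore demonstrate algorithmic correctness and statistical behaviour
under the stated model, not performance on any particular tissue.

`boundaryRecovery()` scores a segmentation against the simulation truth
in retained-CpG ordinal distance with greedy one-to-one matching; with no
predicted boundaries, precision is reported as 1 by convention (nothing
asserted, nothing wrong), documented and tested.  Under the benchmark
conditions (domains of ≥ 50 CpGs, neighbouring $\pi$ differing by
≥ 0.35, depth 30, $\beta = 1$), boundary recall at ±2 CpGs exceeds 0.9.

## Numerical choices

* Segment costs come from prefix sums of $X$ and $X^2$ in double
  precision, with the same summation order in the C++ (PELT) and R (DP)
  paths, so the two recursions see bit-identical costs and their
  tie-breaking matches exactly.  Oracle equality is asserted on
  objectives to $10^{-9}$ and on changepoint sets exactly.
* Ties between split points go to the smallest index, and a cost-neutral
  split is **not** made (the inequality above is strict), so output is
  deterministic.
* PELT pruning uses the $K = 0$ condition, exact because the cost is
  nonnegative.
* Levels are `M/Cov` in double precision; sites with zero coverage are
  dropped at read time since their level is undefined.
* Coverage thresholds are run parameters (default 5; 3 and 10 are common
  alternatives), never hard-coded.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate all inputs in code:
oracle cross-checks use 100 random series of up to 200 points at four
penalties; recovery benchmarks use 20 seeded genomes of twelve 6–12 kb
domains; the robustness trend uses five seeded ~10-Mb genomes
(~10^5 CpGs) thinned to 10–100 %.  These sizes were chosen so the whole
battery runs in about a minute while leaving each statistical conclusion
comfortably away from its threshold.

## Limitations

* A gradually drifting methylation level violates the
  piecewise-constant-mean model and is reported as a staircase.
* The method over-segments very large weak features (PMD-scale) at
  $\beta = 1$; raising the penalty merges them, at the cost of small
  CpG-poor domains.
* DMR calling is descriptive; no error control is provided.
* Only CpG-context methylation is handled; strand counts are merged onto
  the plus-strand C, treating each CpG as one unit (the choice is ours —
  per-strand analysis is not supported).
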