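---
title: "Methods: differential expression, signature scoring and developmental lineage mapping with cellstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-state analysis with cellstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellstate)
library(SummarizedExperiment)
```

# What the package computes

`cellstate` implements the computational core of a class of experiments that
probe transcriptional cell identity in tumor-derived cell lines: a panel of
CRISPR knockout clones (plus a parental line and, optionally, an
overexpressing clone) is profiled by bulk RNA-seq, and the analysis asks
three questions.

1. **Which genes respond?** Differential expression of each clone against
   the parental line at fold-change and FDR thresholds, and the set of
   genes responding in every knockout clone.
2. **Which programs respond?** Pre-ranked gene-set enrichment over GMT
   collections, and per-sample adrenergic (ADRN) versus mesenchymal (MES)
   cell-state scores computed from published signature gene lists by a
   rank-percentile method.
3. **Which developmental state do the clones resemble?** Pearson
   correlation of each clone's transcriptome with every cell of a labeled
   single-cell reference of the developing sympathoadrenal lineage
   (Schwann cell precursors, bridge cells, chromaffin cells,
   sympathoblasts), summarized per cell type, clustered hierarchically,
   and complemented by mutual-exclusivity tests between the knocked-out
   receptor and candidate partner genes on binarized single-cell
   expression.

Every stage is usable on its own; `runPipeline()` chains them and writes a
reproducibility manifest. Because the motivating datasets are external
downloads, the package ships seeded negative-binomial simulators
(`defaultBulkScenario()`, `defaultScScenario()`) that emulate the study
design, so the whole stack is testable offline.

# Differential expression model

Counts for gene $g$ in sample $j$ are modeled as negative binomial with
mean $s_j \mu_{g}$ and variance $\mu + \alpha_g \mu^2$. Size factors $s_j$
are median-of-ratios: the median over genes positive in every sample of
$K_{gj} / (\prod_{j'} K_{gj'})^{1/n}$. Note that factors are defined only
up to the geometric-mean reference: scaling one library by $c$ scales its
factor by $c$ *relative to the others* (all factors also absorb a common
$c^{-1/n}$). For sparse single-cell matrices where no gene is positive
everywhere, `estimateSizeFactorsMOR(fallbackPositiveGeomean = TRUE)`
computes geometric means over positive entries only.

For a two-group comparison (`runDE()`), per-group means $\hat\mu_A,
\hat\mu_B$ come from normalized counts, and the per-gene dispersion is the
method-of-moments estimate $(\widehat{\mathrm{var}} - \hat\mu)/\hat\mu^2$
pooled across the two groups. With two or three replicates per group this
raw estimate has so few degrees of freedom that plugging it into a normal
Wald test is badly anti-conservative. Instead of empirical-Bayes shrinkage
we use the simplest stabilizer consistent with the generative model the
package assumes (one shared $\alpha$ per dataset): each gene's dispersion
is **floored at the dataset-level common dispersion** (the median of the
finite per-gene estimates), then bounded to $[10^{-8}, 10]$. Genes whose
moment estimate exceeds the common value keep their larger (more
conservative) estimate. This restores near-nominal type-I error at
$n = 2$–$3$ per group while retaining full power for large planted fold
changes; both properties are asserted in the test suite.

The reported effect is $\log_2((\hat\mu_B + \epsilon)/(\hat\mu_A +
\epsilon))$ with $\epsilon = 10^{-3}(\hat\mu_A + \hat\mu_B + 1)$, so a
knockout gene with all-zero counts in one group yields a large *finite*
fold change (flagged `zeroInGroup`) rather than $\pm\infty$. The standard
error is the delta-method variance of the log-ratio under the NB model,
`stat = log2fc / se` is the Wald statistic, p-values are two-sided normal,
and adjustment is Benjamini–Hochberg. A gene is called `up` iff
`log2fc > 2` **and** `padj < 0.01` (strict inequalities, both thresholds
configurable via `deConfig()`).

This test is intentionally simple: no dispersion or fold-change shrinkage,
no outlier replacement, no independent filtering. Downstream stages only
consume the fold change, the statistic and the FDR calls, and results are
statistically comparable to — but will not numerically match — full NB-GLM
packages.

# Pre-ranked GSEA

`makeRankedList()` orders genes by the Wald statistic, by default by its
**absolute value** (so sets responding in either direction enrich
positively; a `signed` transform is also provided since published figures
sometimes attribute direction, and the package makes no attempt to guess
which was used). Ties are broken lexicographically so rankings are
reproducible.

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum with weight exponent $p = 1$: at members the sum rises by
$|r_i|^p / \sum_{hits} |r|^p$, elsewhere it falls by $1/(N - N_{hits})$;
ES is the signed maximum deviation and the leading edge contains the
members at or before the extremum (at or after it when ES is negative).
If both extremes have exactly equal magnitude the positive one is
reported. The null (`gseaPreranked()`) is gene-label permutation: random
same-size position sets, one pool per distinct set size, so
$p = (1 + \#\{\text{same-sign null at least as extreme}\})/(1 +
\#\{\text{same-sign null}\})$ with floor $1/(n_{perm}+1)$, and
$NES = ES / \overline{|ES_{null,\,same\ sign}|}$. This is deliberately not
the adaptive multilevel scheme of modern GSEA implementations: it is
deterministic given a seed, exact to its definition, and adequate at the
desk scale the package targets (its p-values saturate at the floor).
Sets outside `[minSize, maxSize]` (defaults 5, 500) are skipped and
recorded.

# Rank-percentile signature scores

Within one sample, a gene's score is its ascending rank percentile:
average ranks for ties, divided by $N$, the number of genes surviving any
upstream filters, so the top gene scores $1$ and percentiles are invariant
under any strictly increasing transform of the column. A signature's score
for a sample is the mean percentile of its genes present in the matrix
(at least half must be present, configurable). Because only within-sample
ranks enter, the scores are *exactly* invariant to per-sample positive
rescaling — normalization cannot change them — which the tests assert as
an identity. Tie handling (average ranks) and the $N$ (not $N-1$)
denominator are implementation-defined choices, stated here because small
published analyses differ on both.

`scoreClones()` reports both MES and ADRN scores per sample plus per-clone
medians, the quantity usually drawn as the summary line in per-clone score
plots.

# Lineage mapping against a single-cell reference

The reference is a labeled gene-by-cell count matrix. Symbols are first
mapped onto the analysis species (`mapOrthologs()`): an explicit
two-column map is filtered to one-to-one pairs (ambiguous pairs dropped
and counted), or, absent a map, case-normalized identity is used — the
common mouse-to-human convention (`Yap1 → YAP1`).

Both matrices are normalized by median-of-ratios and transformed to
$\log_2(x + 1)$ before correlating; the log transform keeps a handful of
high-count genes from dominating the Pearson coefficient, and
`useLog = FALSE` preserves the literal untransformed reading. Each clone's
profile is the mean of its replicates' transformed values. The result is a
`CorrelationMap`: cells by clones, over all shared genes (at least 100
required; no variable-gene selection is applied), with undefined pairs
(constant profiles) recorded rather than silently dropped.
`meanCorrelationByType()` averages within each annotated population — the
expected signature of a mesenchymally reprogrammed clone is highest mean
$r$ for Schwann cell precursors, decreasing over the developmental chain
to chromaffin cells, with sympathoblasts intermediate.

Mutual exclusivity uses the zero/nonzero rule exactly: a gene is
"expressed" in a cell iff its count exceeds zero (median-of-ratios
normalization preserves zero-sets, so raw counts are binarized
internally). `exclusivityTest()` cross-tabulates two genes over all cells
and applies a two-sided Fisher's exact test by the probability-mass rule
(sum over tables at most as probable as observed, margins fixed); an odds
ratio below 1 means exclusive. The reported odds ratio is the sample odds
ratio, with a 0.5 continuity correction applied to the odds ratio only —
never the p-value — when a cell is zero. Because it is ambiguous whether
such tests are best formed gene-versus-gene or gene-versus-population,
`typeEnrichmentTest()` provides the second construction (gene on/off
against membership in a chosen cell type).

Hierarchical clustering of the correlation map uses Manhattan (L1)
distance with complete linkage by default (monotone merge heights;
`average` and `single` are exposed). Cutting the cell axis at the number
of populations recovers the planted types in the synthetic reference;
cutting the clone axis at 2 separates the knockout clones from the
parental line. Dendrograms export as Newick text.

# The synthetic study design

`defaultBulkScenario()` emulates the design of a knockout-clone panel: one
parental line, five knockout clones (C2, C5, C9, C17, C19) and one
overexpressing clone (C1), two biological replicates each; 2,000 genes
with baseline $\log_2$ means uniform on $[3, 10]$ (a wide dynamic range so
rank-percentile scoring has resolution) and a single NB dispersion
$\alpha = 0.05$, typical of cell-line replicates. Planted structure: a
50-gene MES program up $+3$ and a 50-gene ADRN program down $-3$ in every
knockout clone; the knocked-out receptor (`RETL`) at mean zero in the
knockouts; `AXLL` and `YAP1L` moving with the MES program. The
overexpressing clone responds in the **opposite direction at the smaller
magnitude 2**: modeling it as an opposite-but-milder shift places the
parental line between the two response directions, so the clone dendrogram
separates knockouts from parental at its first cut rather than isolating
the single most extreme column — the qualitative geometry the analysis is
designed to exhibit.

`defaultScScenario()` emulates a four-population E13.5 sympathoadrenal
reference, 100 cells per type. The MES program genes are elevated by
$(4, 2.33, 1, 0)$ log2 units and the ADRN program genes by
$(0, 1, 2.33, 4)$ across SCP, bridge, sympathoblast and chromaffin
populations: equal steps along the MES–ADRN axis, wide enough that
per-type mean correlations order reliably and the 4-cut of the cell axis
recovers the types. The exclusivity genes are zero-inflated: per cell,
`AXLL` is "on" with probability 0.85 in SCPs and 0.17 elsewhere, `RETL`
with 0.17 in SCPs and 0.85 elsewhere, `YAP1L` 0.79/0.21 — the published
SCP on-fractions for the corresponding genes, mirror-reversed in the other
populations — and "on" cells draw a zero-truncated NB count at a
$2^6$ mean.

What the emulator deliberately does **not** model: batch effects, UMI or
read-level noise, gene–gene correlation beyond the planted programs,
per-gene dispersion variation, doublets or empty droplets, and
cross-species symbol divergence (bulk and reference share a symbol
universe; `mapOrthologs()` is exercised separately). Passing tests
therefore demonstrate correctness of the *computations* under the stated
generative model, not robustness to every artifact of real data.

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed; each simulator and the GSEA
  permutation null derive named sub-streams from it (a string hash modulo
  $2^{31}-1$), so the bulk and single-cell matrices can be regenerated
  independently and reruns are bit-identical.
* Dispersion bounds $[10^{-8}, 10]$; fold-change stabilizer
  $\epsilon = 10^{-3}(\hat\mu_A + \hat\mu_B + 1)$.
* Median convention: the size-factor median averages the two middle
  *ratios* arithmetically for even counts (log-space implementations
  average geometrically; the two coincide for odd counts).
* Ties: ranked lists break score ties lexicographically; rank percentiles
  average tied ranks; an exactly balanced ES extremum reports the
  positive side.
* Degenerate inputs are errors with actionable messages rather than NAs:
  a set covering the whole ranked universe, a signature mostly absent
  from the matrix, a 2x2 table with a zero margin (p = 1, odds ratio
  flagged), all-identical expression columns (percentiles
  $(N+1)/2N$ with a warning), conflicting planted programs, 0-based
  MatrixMarket indices.
* Problem sizes used throughout the tests and the acceptance script —
  2,000 genes, 14 bulk samples, 400 reference cells, 1,000 permutations —
  are the package's chosen desk scale: large enough for stable
  calibration estimates, small enough to iterate on.

# Known limitations

* The DE test is two-group only (no covariates, no likelihood-ratio
  tests) and does not reproduce any specific NB-GLM tool's numbers.
* The permutation GSEA p-value saturates at $1/(n_{perm}+1)$; very small
  p-values require raising `nPerm`.
* Signature scoring assumes the signature lists are meaningful for the
  matrix's gene universe; it checks presence, not biology.
* The lineage map takes the reference's population labels as given and
  performs no pseudotime or re-clustering of the reference itself.
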