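---
title: "Methods: tiled DMR signatures, variance decomposition, and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled DMR signatures, variance decomposition, and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmethatlas)
```

## Scope and model

`tmethatlas` analyses cohorts of RRBS methylomes from tissue memory T cell
populations. The atomic datum is a per-CpG pair of counts
(methylated reads, total reads); methylation is always the fraction
`m/n` internally and is rendered on a 0–100 percent scale only at export.
Coordinates are 0-based half-open everywhere inside the package; the only
1-based surface is the Bismark coverage dialect, converted at read/write
time. Calls are assumed strand-merged (one record per CpG site); gene
strand is used only to orient TSS, UTRs and distances. Missing CpGs — by
sequence context or RRBS capture — are represented by absence, never by a
zero, so "unmethylated" and "unobserved" cannot be conflated.

### Tiling and the DMR rule

The genome is cut into a fixed, non-overlapping 500 bp grid anchored at
coordinate 0 (`build_tile_grid()`; a trailing partial tile is dropped).
Per sample and tile, methylation is the coverage-weighted ratio
`sum(meth)/sum(total)` over CpGs with at least `min_cov_per_cpg` (default 3)
reads. Population values are unweighted means over replicates — pooled
libraries already average donors, and weighting by depth would let deep
libraries dominate. In the default *strict* mode a population tile is
missing whenever any replicate is missing, so every pairwise comparison
rests on complete data.

A tile is a DMR for an (A, B) population pair iff

1. both population values exist,
2. both populations cover at least `min_cpgs` (default 5) CpGs in the tile
   — the count is a property of the *comparison*, guarding against
   asymmetric-coverage artifacts — and
3. `|mean_A - mean_B| >= delta` with `delta = 0.15`.

The threshold is read as 15 percentage points of tile-mean methylation.
An alternative reading — at least 15% of the tile's CpGs individually
differential — exists; we implement only the tile-mean semantics, which
matches how tile-level methylation is quantified and displayed throughout
this kind of analysis. Comparisons use a `1e-9` absolute tolerance at the
boundary so that ratios equal to the threshold by construction are not lost
to floating-point representation.

Compiled tissue-specific sets are unions over all pairwise tissue
comparisons within one lineage × CD69 subset, in deterministic genomic
order, carrying per-pair signed differences and the maximum absolute
difference. `top_decile_dmrs()` retains DMRs at or above the 90th
percentile of that maximum (R's default quantile definition; ties at the
cutoff are all kept). No sliding windows, no merging of adjacent tiles, no
per-tile significance testing (beta-binomial or Fisher models and
BSmooth-style smoothing are deliberately out of scope): the rule is a
deterministic effect-size filter, which is what makes it exactly testable.

### PMD methylation

Partially methylated domains are an *input* (previously published interval
sets), never discovered de novo. `pmd_weighted_methylation()` computes the
same coverage-weighted ratio per PMD and a global value that aggregates raw
counts over all PMDs — hence invariant to how the domains are partitioned
into sub-intervals. Overlapping PMD inputs are rejected rather than
silently merged.

### Variance decomposition and clustering

On the compiled DMR × sample matrix:

* `donor_variance()` reports, per sample, the variance and CV of its DMR
  methylation values. The population denominator (n) is the default and a
  sample-variance switch is provided; published summary figures of this
  kind do not pin the convention down (reported "variance" ranges of
  0.044–0.06 next to CVs of 4–10% are dimensionally consistent only if the
  former are standard deviations), so both statistics are emitted and the
  choice is documented rather than inferred.
* Missing entries are mean-imputed per DMR before PCA/clustering —
  variance-conservative and keeps all samples. Rows missing everywhere are
  dropped with a warning.
* `pca_fit()` treats samples as observations and DMRs as variables
  (per-DMR centring, no variance scaling). Signs follow a fixed convention
  (largest-magnitude loading positive), making scores deterministic.
  `pca_project()` uses training means and loadings only, so training
  samples reproduce their fitted scores and the training mean profile maps
  to the origin; blood samples can be projected into a tissue-trained space
  without influencing it.
* `manova_tissue()` fits a one-way MANOVA of the first k (default 2,
  the two displayed components) PC scores on tissue and reports Wilks' Λ
  with Rao's approximate F. The F is the tissue-to-donor variance ratio:
  the residual is the between-donor variation within tissues. With k = 1
  the statistic reduces to the one-way ANOVA F (verified in tests).
  Singular within-group covariance is reported as an error, never silently
  regularised.
* Heatmap-style structure uses per-DMR Z-scores (population sd; constant
  rows map to zero) and Euclidean/Ward (`ward.D2`) clustering on either
  axis, with flat labels from cutting the tree — standard heatmap practice;
  distance and linkage are configurable.

### Annotation

The promoter is TSS ± 3 kb in strand-oriented coordinates regardless of
gene-body overlap; on the minus strand the genomic window is
`[tss - 2999, tss + 3001)`, the exact mirror image of the plus-strand
window (verified against mirrored gene constructions). A DMR may carry any
subset of {promoter, 5'UTR, exon, intron, 3'UTR}; `intergenic` means none.
Composition fractions are therefore per-feature, not a partition, and may
sum above 1. The regulatory filter keeps promoter-or-intron DMRs, the
subset used for signature clustering. Gene ranking counts regulatory DMRs
per gene, breaking ties by the largest compiled difference and then gene id
— a declared convention, since no canonical ranking rule exists for
"top genes by DMR load". One transcript per gene is assumed; multi-isoform
collapse is the data supplier's job.

### Association statistics

Group comparisons use two-sided Mann–Whitney rank-sum tests: exact null for
combined n ≤ 20 without ties, otherwise the tie- and continuity-corrected
normal approximation. Stars follow the conventional four-level scheme
(\*\*\*\* p < 0.0001 … \* p < 0.05). Raw p-values are reported by default;
BH correction is available behind a flag. Methylation–expression coupling
is ordinary least squares of linear-scale expression on the methylation
fraction, p from the two-sided t-test on the slope; zero methylation
variance is an error, not a zero.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions the package is validated
under. Defaults: six tissues (Bm, In, Sp, Lu, Sk, Bl), three individual
donors per population, ~100 bp mean CpG spacing, 40% CpG capture, NB(mean
30, size 5) read depth, 500 bp planted DMRs with `dmr_delta = 0.4`, donor
offset sd 0.02, and ten multi-kilobase PMDs with per-tissue levels spread
over [0.5, 0.7]. Donor pooling averages the *true* methylation of pool
members (default 3, matching common pooling designs) before read sampling.

Design choices that matter for what the tests mean:

* **Fragment-wise capture.** RRBS captures restriction fragments, so
  covered CpGs arrive in contiguous blocks shared across a cohort's
  samples. The generator groups CpGs into fragments (mean 10 CpGs) and
  captures whole fragments to a 40% CpG quota. Independent per-CpG capture
  at 40% would leave almost no 500 bp tile with ≥ 5 covered CpGs and make
  the tile rule vacuously untestable.
* **Tile-coherent baseline.** Baseline methylation is a three-state
  mixture (CpG-island-like low, intermediate, background high), with one
  state and one Beta-drawn level per 500 bp tile, because real methylation
  is autocorrelated and DMR calling must be exercised on coherent tiles.
* **Ascertainable planting.** Planted DMRs are placed only on fully
  captured tiles with ≥ 5 CpGs outside PMDs, and the shift direction is
  chosen to keep levels inside [0.01, 0.99] (an infeasible `dmr_delta`
  errors out rather than clipping silently). Recovery statistics are
  therefore conditional on ascertainment, as in any sequencing study:
  truth that cannot be observed is not planted.
* **Effects add on the methylation scale** with clamping to [0.01, 0.99];
  a logit-scale alternative would avoid clamping but break the exact
  analytic expectations the tests rely on.
* **PMDs replace the baseline** with the tissue's level (no donor offset,
  no DMR delta inside PMDs), so the planted per-tissue level is exactly
  the per-CpG truth and recovery can be checked against plain binomial
  intervals.
* **One RNG stream per cohort**, seeded from the config; identical seeds
  give byte-identical cohorts, and the caller's RNG state is restored.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: bisulfite conversion error, read-level biases and
mapping artifacts, strand asymmetries, copy-number variation, correlated
(haplotype-scale) donor effects, cell-composition drift within a
population, and genome-scale CpG landscape heterogeneity. The generator's
donor effects are constant within baseline-state classes, a crude but
controllable stand-in for coordinated inter-individual variation.

## Calibration regimes used in the tests

The acceptance tests run at deliberately modest problem sizes chosen as
realistic desk-scale analogues: a 1 Mb genome (2000 tiles, ~10⁴ CpGs) with
200 planted DMRs for recovery; 60 kb cohorts for the 200-replicate MANOVA
null; 150 kb cohorts for the variance-regime replicates. The
tissue-to-donor regime is constructed, not tuned: with T tissues and one
affected tissue per DMR, the between-tissue variance of true tile means is
`delta^2 (T-1)/T^2`; with T = 3 and `delta = 0.2`, a donor sd of 0.0667
makes it exactly twice the donor variance. In that regime the MANOVA F
exceeds 1 in essentially all replicates and column dendrograms group
samples by tissue in the large majority — the qualitative behaviour
expected when tissue variation is roughly twice donor variation. The
published F range from the motivating atlas (1.65–2.27) depends on
controlled-access data and is not a target of these tests.

## Known limitations

* The DMR rule is effect-size-only; at low coverage the tile means are
  noisy and the false-positive rate is governed entirely by coverage and
  replicate count (tests verify it falls monotonically with coverage).
* Mean imputation before PCA shrinks the variance of poorly covered DMRs
  toward zero; with systematically missing populations this biases scores.
* MANOVA p-values assume approximate normality of PC scores; on tile
  fractions near 0 or 1 the approximation degrades. The null-calibration
  test covers the regime the package recommends, not every corner.
* `donor_variance()` describes within-sample dispersion across DMRs; it is
  not a variance-components decomposition.
* Gene ranking depends on the supplied (single-transcript) gene models;
  isoform choice upstream changes promoter windows and hence the ranking.
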