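# tmethatlas

Tiled methylome analysis for tissue memory T cell atlases.

## The problem

Memory T lymphocytes (Tm) persist in tissues such as bone marrow, intestine,
spleen, lung and skin; CD69⁺ Tm are regarded as tissue-resident (Trm). Their
DNA methylomes, measured by reduced representation bisulfite sequencing
(RRBS), carry tissue-specific imprinting signatures. Extracting those
signatures from per-CpG methylation call tables requires a chain of standard
but detail-sensitive steps — tiling, coverage weighting, differential
calling, variance decomposition, annotation — each of which is easy to get
subtly wrong. `tmethatlas` implements that chain as a tested R package and
validates every step against synthetic cohorts with planted ground truth.

## The method

For each sample, per-CpG calls (methylated reads `m_i`, total reads `n_i`)
are summarised on a fixed, non-overlapping 500 bp grid anchored at
coordinate 0 by the **coverage-weighted tile methylation**

```
M(tile) = Σ_i m_i / Σ_i n_i    over CpGs in the tile with n_i ≥ 3
```

Replicates are averaged per population (tissue × lineage × CD69). A tile is
a **differentially methylated region (DMR)** for a pair of populations when

* both populations cover ≥ 5 CpGs in the tile, and
* the absolute difference of the population means is ≥ 0.15
  (15 percentage points).

The union of tiles passing in any pairwise tissue comparison within one
lineage × CD69 subset is the subset's **compiled tissue-specific DMR set**.
On that matrix the package computes donor variance and CV per sample, PCA
(per-DMR centring, no scaling) with projection of held-out samples, a
one-way MANOVA of the leading PC scores on tissue (Wilks' Λ, Rao's
approximate F — the tissue-to-donor variance ratio), per-DMR Z-scores and
Euclidean/Ward hierarchical clustering. DMRs are annotated against gene
models (promoter = TSS ± 3 kb strand-oriented, 5'UTR, exon, intron, 3'UTR;
multi-flag membership), filtered to putatively regulatory (promoter or
intron) DMRs, and genes are ranked by their regulatory DMR load. Weighted
methylation over externally supplied partially methylated domains (PMDs),
Mann–Whitney rank tests with the conventional star scheme, and simple
linear regression of expression on methylation round out the toolkit.

The synthetic-data generator (`simulate_cohort()`) emulates the atlas study
design — shared CpG landscape, fragment-wise RRBS capture of ~40% of CpGs,
negative-binomial depth, tile-coherent bimodal baseline, planted 500 bp
tissue-specific DMRs, per-donor offsets, donor pooling, and per-tissue PMD
levels — and returns the planted truth for recovery testing.

## Worked example

```r
library(tmethatlas)

cfg <- sim_config(seed = 42, chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                  donors_per_tissue = 3L, n_planted_dmrs = 200L, pmd_count = 0L)
cohort <- simulate_cohort(cfg)                       # 18 samples, 6 tissues
tiles  <- build_tile_grid(cfg$chrom_lengths)         # 2000 x 500 bp tiles
tm     <- tile_matrix(cohort$calls, tiles)
dmrs   <- compile_subset_dmrs(tm, cohort$sheet, lineage = "CD4", cd69 = "pos")
dmrs
#> <dmr_set> [CD4 pos] 199 DMRs over 15 pairwise comparison(s)
genome_fraction(dmrs, cfg$chrom_lengths)             # 0.0995 -> ~10 % of 1 Mb

mat    <- impute_row_means(tm_restrict(tm, dmrs)$values)
fit    <- pca_fit(mat, k = 2)
tissue <- cohort$sheet$tissue[match(rownames(fit$scores), cohort$sheet$sample_id)]
manova_tissue(fit$scores, tissue, k = 2)
#> <manova_result> Wilks F = 2067.016 (df 10, 22), p = 2.67e-30

ann <- annotate_dmrs(dmrs, cohort$genes)
round(feature_composition(ann), 3)
#>  promoter     utr5     exon   intron     utr3 intergenic any_feature regulatory
#>     1.000    0.533    0.719    0.698    0.111      0.000       1.000      1.000
```

199 of the 200 planted DMR tiles are recovered (one falls below the CpG
count rule in one population), no false tiles are called, tissue separation
dwarfs donor variation (F ≫ 1), and — because the generator anchors a gene
promoter or intron at every planted DMR — the annotation flags reflect that
construction. `run_pipeline("all", pipeline_config(outdir = "out"))` runs
the same chain end to end from files and writes a manifest; a thin CLI
wrapper is installed at `inst/cli/tmethatlas.R`.

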