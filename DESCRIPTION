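Package: tmethatlas
Title: Tiled Methylome Analysis for Tissue Memory T Cell Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for atlas-style analysis of reduced-representation
    bisulfite sequencing (RRBS) methylomes of tissue memory T cell
    populations: fixed 500 bp tiling of CpG call tables, coverage-weighted
    tile methylation, pairwise differentially methylated region (DMR)
    calling and compilation of tissue-specific DMR signatures, weighted
    methylation over partially methylated domains (PMDs), donor-variance
    statistics, PCA with held-out sample projection and MANOVA
    tissue-versus-donor decomposition, hierarchical signature clustering,
    genomic-feature annotation of DMRs, rank-based group comparisons and
    methylation-expression regression. A synthetic-cohort generator with
    planted ground truth supports end-to-end validation of every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
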