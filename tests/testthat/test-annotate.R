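# build a dmr_set directly from tile coordinates
dmrs_at <- function(chrom, start, diffs = NULL, chrom_len = 200000L) {
  tiles <- build_tile_grid(stats::setNames(rep(chrom_len, length(unique(chrom))),
                                           unique(chrom)))
  ids <- paste0(chrom, ":", start, "-", start + 500L)
  if (is.null(diffs)) diffs <- rep(0.3, length(ids))
  pw <- list("A|B" = data.frame(tile_id = ids, chrom = chrom, start = start,
                                end = start + 500L, diff = diffs))
  compile_dmr_set(pw, tiles)
}

test_that("feature flags follow the overlap rules", {
  gm <- tiny_gene_model()
  # gA (+, tss 10000): intron 2 spans [12800, 15000); rows are in genomic
  # order, so address them by tile id
  set <- dmrs_at("chr1", c(13000L, 9500L, 100000L))
  ann <- annotate_dmrs(set, gm)
  intron_dmr <- "chr1:13000-13500"
  prom_dmr <- "chr1:9500-10000"
  far_dmr <- "chr1:100000-100500"
  expect_true(ann$flags[intron_dmr, "intron"])
  expect_false(any(ann$flags[intron_dmr, c("exon", "utr5", "utr3")]))
  expect_false(ann$flags[intron_dmr, "promoter"])  # window ends at tss + 3 kb
  # DMR straddling tss - 100: promoter, negative (upstream) distance
  expect_true(ann$flags[prom_dmr, "promoter"])
  g <- ann$genes[ann$genes$tile_id == prom_dmr &
                   ann$genes$relation == "promoter", ]
  expect_equal(g$distance_to_tss, 9750L - 10000L)
  # far from every gene: intergenic
  expect_true(ann$flags[far_dmr, "intergenic"])
  expect_false(any(ann$flags[far_dmr, colnames(ann$flags) != "intergenic"]))
})

test_that("distance to TSS is strand-oriented", {
  gm <- tiny_gene_model()
  # gB is minus strand with tss 45999; a DMR at [47000, 47500) is upstream
  set <- dmrs_at("chr1", 47000L)
  ann <- annotate_dmrs(set, gm)
  g <- ann$genes[ann$genes$gene_id == "gB" & ann$genes$relation == "promoter", ]
  expect_equal(g$distance_to_tss, 45999L - 47250L)  # negative = upstream
})

test_that("flags match an all-pairs quadratic oracle, including mirrored genes", {
  set.seed(801)
  L <- 400000L
  clipped <- function(ex, lo, hi) {
    s <- pmax(ex[, 1], lo); e <- pmin(ex[, 2], hi)
    .b(s[s < e], e[s < e])
  }
  # random 2-exon genes on both strands
  mk_gene <- function(id, strand) {
    s <- sample.int(L - 12000L, 1L)
    l1 <- sample(300:800, 1L); gap <- sample(200:1500, 1L)
    l2 <- sample(300:800, 1L)
    exons <- .b(c(s, s + l1 + gap), c(s + l1, s + l1 + gap + l2))
    g <- data.frame(gene_id = id, chrom = "chr1", strand = strand,
                    start = min(exons[, 1]), end = max(exons[, 2]),
                    stringsAsFactors = FALSE)
    g$exons <- list(exons)
    g$utr5 <- list(clipped(exons, min(exons), min(exons) + 150L))
    g$utr3 <- list(clipped(exons, max(exons) - 150L, max(exons)))
    g
  }
  base <- do.call(rbind, lapply(1:25, function(i) {
    mk_gene(sprintf("g%02d", i), sample(c("+", "-"), 1))
  }))
  # exact coordinate mirrors on the opposite strand
  mirror <- base
  mirror$gene_id <- paste0(base$gene_id, "m")
  mirror$strand <- ifelse(base$strand == "+", "-", "+")
  mirror$start <- L - base$end
  mirror$end <- L - base$start
  flip <- function(m) .b(rev(L - m[, 2]), rev(L - m[, 1]))
  mirror$exons <- lapply(base$exons, flip)
  mirror$utr5 <- lapply(base$utr5, flip)
  mirror$utr3 <- lapply(base$utr3, flip)
  gm <- gene_model(rbind(base, mirror))

  starts <- sample(seq(0L, L - 500L, by = 500L), 500L)
  set <- dmrs_at("chr1", starts, chrom_len = L)
  ann <- annotate_dmrs(set, gm)

  flank <- 3000L
  introns <- gene_introns(gm)
  oracle_flags <- function(ds, de) {
    want <- stats::setNames(rep(FALSE, 5),
                            c("promoter", "utr5", "exon", "intron", "utr3"))
    for (j in seq_len(nrow(gm))) {
      tss <- gm$tss[j]
      pw <- if (gm$strand[j] == "+") c(tss - flank, tss + flank)
            else c(tss - flank + 1L, tss + flank + 1L)
      if (oracle_overlap(ds, de, pw[1], pw[2])) want["promoter"] <- TRUE
      for (feat in c("utr5", "exon", "utr3")) {
        blocks <- if (feat == "exon") gm$exons[[j]] else gm[[feat]][[j]]
        for (r in seq_len(NROW(blocks))) {
          if (oracle_overlap(ds, de, blocks[r, 1], blocks[r, 2])) {
            want[feat] <- TRUE
          }
        }
      }
      for (r in seq_len(NROW(introns[[j]]))) {
        if (oracle_overlap(ds, de, introns[[j]][r, 1], introns[[j]][r, 2])) {
          want["intron"] <- TRUE
        }
      }
    }
    want
  }
  for (i in seq_len(n_dmrs(set))) {
    want <- oracle_flags(set$tiles$start[i], set$tiles$end[i])
    expect_identical(unname(ann$flags[i, names(want)]), unname(want))
    expect_identical(unname(ann$flags[i, "intergenic"]), !any(want))
  }

  # strand correctness: the mirror image of every DMR gets identical flags
  mirror_ids <- paste0("chr1:", L - set$tiles$end, "-", L - set$tiles$start)
  set_m <- dmrs_at("chr1", L - set$tiles$end, chrom_len = L)
  ann_m <- annotate_dmrs(set_m, gm)
  got <- ann_m$flags[match(mirror_ids, rownames(ann_m$flags)), ]
  expect_identical(unname(got), unname(ann$flags))
})

test_that("feature composition counts multi-flag DMRs per feature", {
  gm <- tiny_gene_model()
  set <- dmrs_at("chr1", c(10000L, 100000L))  # one genic (utr5+exon+promoter), one intergenic
  ann <- annotate_dmrs(set, gm)
  comp <- feature_composition(ann)
  expect_equal(unname(comp["promoter"]), 0.5)
  expect_equal(unname(comp["exon"]), 0.5)
  expect_equal(unname(comp["any_feature"]), 0.5)
  all_inter <- annotate_dmrs(dmrs_at("chr1", c(100000L, 150000L)), gm)
  expect_equal(unname(feature_composition(all_inter)["any_feature"]), 0)
})

test_that("the regulatory filter keeps promoter/intron DMRs only and is idempotent", {
  gm <- tiny_gene_model()
  # 15400: inside utr3/exon of gA but > 3 kb from tss 10000 -> dropped;
  # 13000: intron -> kept; 100000: intergenic -> dropped
  set <- dmrs_at("chr1", c(15500L, 13000L, 100000L))
  ann <- annotate_dmrs(set, gm)
  utr_dmr <- "chr1:15500-16000"
  expect_false(ann$flags[utr_dmr, "promoter"] || ann$flags[utr_dmr, "intron"])
  expect_true(ann$flags[utr_dmr, "utr3"])
  reg <- filter_regulatory(ann)
  expect_equal(reg$tiles$start, 13000L)
  # re-annotation of the filtered set is a no-op on flags
  ann2 <- annotate_dmrs(reg, gm)
  expect_identical(ann2$flags["chr1:13000-13500", ],
                   ann$flags["chr1:13000-13500", ])
  expect_true(all(reg$tiles$tile_id %in% ann$set$tiles$tile_id))
})

test_that("gene ranking orders by DMR count, effect size, then id", {
  gm <- tiny_gene_model()
  # gA gets two intron/promoter DMRs, gB and gC one promoter DMR each
  set <- dmrs_at("chr1", c(9500L, 13000L, 43500L, 69000L),
                 diffs = c(0.2, 0.2, 0.5, 0.5))
  ann <- annotate_dmrs(set, gm)
  rk <- rank_genes(ann, n = 10)
  expect_equal(rk$gene_id[1], "gA")
  expect_equal(rk$n_dmrs[1], 2L)
  # gB and gC tie on count and effect: lexicographic
  expect_equal(rk$gene_id[2:3], c("gB", "gC"))
  expect_equal(nrow(rank_genes(ann, n = 2)), 2L)
  expect_error(rank_genes(ann, n = 0), "positive")
})

test_that("genes on unknown chromosomes are skipped with a warning", {
  gm <- tiny_gene_model()
  gm$chrom <- c("chr1", "chrX", "chr1")
  set <- dmrs_at("chr1", 13000L)
  expect_warning(ann <- annotate_dmrs(set, gm), "skipping 1 gene")
  expect_true(ann$flags[1, "intron"])
})
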