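test_that("tile grid is floor division per chromosome, disjoint and covering", {
  expect_equal(nrow(build_tile_grid(c(c1 = 1250L))), 2L)
  expect_equal(nrow(build_tile_grid(c(c1 = 499L))), 0L)
  g <- build_tile_grid(c(c1 = 1000000L))
  expect_equal(nrow(g), 2000L)
  expect_equal(g$start, seq(0L, 999500L, by = 500L))
  expect_true(all(g$end - g$start == 500L))
  expect_equal(g$end[-2000], g$start[-1])  # disjoint, contiguous
})

test_that("tile methylation is the coverage-weighted ratio with a per-CpG filter", {
  tiles <- build_tile_grid(c(chr1 = 1000L))
  calls <- cpg_calls("chr1", c(10L, 400L, 600L), c(7L, 0L, 1L),
                     c(7L, 5L, 2L), "s")
  col <- tile_methylation(calls, tiles, min_cov_per_cpg = 3L)
  expect_equal(col$values[1], 7 / 12)     # (7 + 0) / (7 + 5)
  expect_equal(col$cpg_count[1], 2L)
  expect_true(is.na(col$values[2]))       # single 2-read CpG filtered out
  expect_equal(col$cpg_count[2], 0L)
})

test_that("tile methylation equals the per-CpG brute-force oracle exactly", {
  set.seed(501)
  tiles <- build_tile_grid(c(chr1 = 20000L, chr2 = 20000L))
  calls <- rand_calls(150, max_pos = 20000L)
  got <- tile_methylation(calls, tiles)
  want <- oracle_tile_meth(calls, tiles)
  expect_identical(got$cpg_count, want$cpg_count)
  expect_identical(got$values, want$values)  # same integer-ratio arithmetic
})

test_that("population means aggregate replicates unweighted with strict missingness", {
  tiles <- build_tile_grid(c(chr1 = 1000L))
  calls <- list(
    a = cpg_calls("chr1", c(10L, 600L), c(2L, 5L), c(10L, 10L), "a"),
    b = cpg_calls("chr1", 10L, 4L, 10L, "b")
  )
  sheet <- sample_sheet(c("a", "b"), c("Bm", "Bm"), c("CD4", "CD4"),
                        c("pos", "pos"), list("d1", "d2"))
  tm <- tile_matrix(calls, tiles)
  strict <- population_means(tm, sheet)
  expect_equal(strict$values[1, 1], 0.3)           # mean(0.2, 0.4)
  expect_true(is.na(strict$values[2, 1]))          # b missing tile 2
  lenient <- population_means(tm, sheet, mode = "lenient")
  expect_equal(lenient$values[2, 1], 0.5)
  expect_equal(strict$cpg_count[1, 1], 1L)         # min over replicates
})

test_that("the DMR rule is exact at its boundaries", {
  tiles <- build_tile_grid(c(chr1 = 1500L))
  mk <- function(vals, counts) {
    structure(list(
      tiles = tiles,
      values = matrix(vals, ncol = 2, dimnames = list(tiles$tile_id, c("A", "B"))),
      cpg_count = matrix(counts, ncol = 2, dimnames = list(tiles$tile_id, c("A", "B"))),
      tile_size = 500L), class = "tile_matrix")
  }
  # delta boundary: 0.149 fails, 0.150 passes (strict >= 0.15)
  pop <- mk(c(0.10, 0.10, 0.5, 0.249, 0.250, 0.5), rep(6L, 6))
  got <- call_dmrs_pairwise(pop, "A", "B")
  expect_equal(got$tile_id, tiles$tile_id[2])
  expect_equal(got$diff, -0.15)
  # CpG-count boundary: 4 CpGs fails, 5 passes, in either population
  pop <- mk(rep(c(0.1, 0.4), each = 3), c(5L, 5L, 4L, 5L, 4L, 5L))
  got <- call_dmrs_pairwise(pop, "A", "B")
  expect_equal(got$tile_id, tiles$tile_id[1])
})

test_that("pairwise calling is antisymmetric and invariant to relabeling", {
  co <- small_cohort(seed = 31)
  tiles <- build_tile_grid(co$config$chrom_lengths)
  pop <- population_means(tile_matrix(co$calls, tiles), co$sheet)
  ab <- call_dmrs_pairwise(pop, "Bm.CD4.pos", "Sk.CD4.pos")
  ba <- call_dmrs_pairwise(pop, "Sk.CD4.pos", "Bm.CD4.pos")
  expect_equal(ab$tile_id, ba$tile_id)
  expect_equal(ab$diff, -ba$diff)

  # sample column permutation does not change the call
  perm <- rev(names(co$calls))
  pop2 <- population_means(tile_matrix(co$calls[perm], tiles), co$sheet)
  ab2 <- call_dmrs_pairwise(pop2, "Bm.CD4.pos", "Sk.CD4.pos")
  expect_equal(ab2, ab)

  # chromosome relabeling relabels, but does not change, the calls
  relab <- lapply(co$calls, function(x) {
    cpg_calls(sub("chr", "scaffold", x$chrom), x$pos, x$meth, x$total,
              sample_id(x))
  })
  lens2 <- stats::setNames(co$config$chrom_lengths,
                           sub("chr", "scaffold", names(co$config$chrom_lengths)))
  pop3 <- population_means(tile_matrix(relab, build_tile_grid(lens2)), co$sheet)
  ab3 <- call_dmrs_pairwise(pop3, "Bm.CD4.pos", "Sk.CD4.pos")
  expect_equal(sub("scaffold", "chr", ab3$tile_id), ab$tile_id)
  expect_equal(ab3$diff, ab$diff)
})

test_that("full pairwise calling matches a brute-force tile loop on a cohort", {
  co <- small_cohort(seed = 32)
  tiles <- build_tile_grid(co$config$chrom_lengths)
  tm <- tile_matrix(co$calls, tiles)
  pop <- population_means(tm, co$sheet)
  got <- call_dmrs_pairwise(pop, "Bm.CD4.pos", "Lu.CD4.pos")
  # oracle: loop over tiles, recompute the rule from the population matrix
  hits <- character(); diffs <- numeric()
  for (i in seq_len(nrow(tiles))) {
    a <- pop$values[i, "Bm.CD4.pos"]; b <- pop$values[i, "Lu.CD4.pos"]
    ca <- pop$cpg_count[i, "Bm.CD4.pos"]; cb <- pop$cpg_count[i, "Lu.CD4.pos"]
    if (!is.na(a) && !is.na(b) && ca >= 5 && cb >= 5 && abs(a - b) >= 0.15) {
      hits <- c(hits, tiles$tile_id[i]); diffs <- c(diffs, a - b)
    }
  }
  expect_equal(got$tile_id, hits)
  expect_equal(got$diff, diffs)
})

test_that("compiled sets are unions with per-pair diffs and max_abs_diff", {
  tiles <- build_tile_grid(c(chr1 = 2000L))
  pw <- list(
    "A|B" = data.frame(tile_id = tiles$tile_id[c(1, 3)],
                       chrom = "chr1", start = c(0L, 1000L),
                       end = c(500L, 1500L), diff = c(0.2, -0.3)),
    "A|C" = data.frame(tile_id = tiles$tile_id[3], chrom = "chr1",
                       start = 1000L, end = 1500L, diff = 0.5)
  )
  set <- compile_dmr_set(pw, tiles)
  expect_equal(n_dmrs(set), 2L)
  expect_equal(set$tiles$max_abs_diff, c(0.2, 0.5))
  expect_equal(set$passing[[1]], "A|B")
  expect_equal(sort(set$passing[[2]]), c("A|B", "A|C"))
  empty <- compile_dmr_set(list("A|B" = pw[["A|B"]][0, ]), tiles)
  expect_equal(n_dmrs(empty), 0L)
})

test_that("top-decile selection keeps >= 90th percentile with ties included", {
  tiles <- build_tile_grid(c(chr1 = 500L * 1000L))
  mk_set <- function(diffs) {
    k <- seq_along(diffs)
    pw <- list("A|B" = data.frame(
      tile_id = tiles$tile_id[k], chrom = rep("chr1", length(k)),
      start = tiles$start[k], end = tiles$end[k], diff = diffs))
    compile_dmr_set(pw, tiles)
  }
  ten <- mk_set(seq(0.15, 0.60, length.out = 10))
  expect_equal(top_decile_dmrs(ten)$tiles$max_abs_diff, 0.60)
  tied <- mk_set(rep(0.3, 8))
  expect_equal(n_dmrs(top_decile_dmrs(tied)), 8L)
  set.seed(502)
  d <- runif(1000, 0.15, 1)
  big <- mk_set(d)
  got <- sort(top_decile_dmrs(big)$tiles$max_abs_diff)
  want <- sort(d, decreasing = TRUE)[1:100]          # sort-and-slice oracle
  expect_equal(got, sort(want))
  expect_error(top_decile_dmrs(mk_set(numeric())), "empty")
})

test_that("genome fraction is total DMR bp over genome bp", {
  tiles <- build_tile_grid(c(chr1 = 100000L))
  pw <- list("A|B" = data.frame(
    tile_id = tiles$tile_id[1:10], chrom = "chr1",
    start = tiles$start[1:10], end = tiles$end[1:10], diff = rep(0.2, 10)))
  set <- compile_dmr_set(pw, tiles)
  expect_equal(genome_fraction(set, c(chr1 = 100000L)), 0.05)
  expect_equal(genome_fraction(compile_dmr_set(list("A|B" = pw[["A|B"]][0, ]),
                                               tiles), c(chr1 = 100000L)), 0)
  set.seed(503)
  keep <- sample(200, 37)
  pw2 <- list("A|B" = data.frame(
    tile_id = tiles$tile_id[keep], chrom = "chr1", start = tiles$start[keep],
    end = tiles$end[keep], diff = runif(37, 0.15, 0.5)))
  s2 <- compile_dmr_set(pw2, tiles)
  expect_equal(genome_fraction(s2, c(chr1 = 100000L)),
               sum(s2$tiles$end - s2$tiles$start) / 100000)
})

test_that("false-positive tiles fall with coverage and vanish on deep null cohorts", {
  fp_rate <- function(cov, seed) {
    co <- simulate_cohort(sim_config(
      seed = seed, chrom_lengths = c(chr1 = 120000L),
      tissues = c("Bm", "Sk"), donors_per_tissue = 2L,
      n_planted_dmrs = 0L, pmd_count = 0L, donor_sd = 0,
      coverage_mean = cov, coverage_dispersion = 10))
    tiles <- build_tile_grid(co$config$chrom_lengths)
    set <- compile_subset_dmrs(tile_matrix(co$calls, tiles), co$sheet,
                               "CD4", "pos")
    n_dmrs(set) / nrow(tiles)
  }
  rates <- vapply(c(8, 30, 120), fp_rate, numeric(1), seed = 33)
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[3], 0)
})
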