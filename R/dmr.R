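## Tiled DMR calling.
##
## The genome is cut into a fixed, non-overlapping 500 bp grid anchored at
## coordinate 0. A tile is a DMR for a pair of populations when both
## population means exist, both populations cover >= 5 CpGs in the tile, and
## the absolute difference of the coverage-weighted tile methylation means
## is >= 0.15 (15 percentage points). Compiled tissue-specific sets are the
## union of tiles passing in any pairwise comparison within one
## lineage x CD69 subset.

#' Build the fixed tile grid
#'
#' Tiles `[0, tile_size)`, `[tile_size, 2*tile_size)`, ... per chromosome;
#' a trailing partial tile is dropped.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param tile_size tile width in bp (default 500).
#' @return data frame `chrom`, `start`, `end`, `tile_id` in genomic order.
#' @export
build_tile_grid <- function(chrom_lengths, tile_size = 500L) {
  stopifnot(tile_size > 0L, !is.null(names(chrom_lengths)))
  n <- as.integer(chrom_lengths) %/% as.integer(tile_size)
  chrom <- rep(names(chrom_lengths), n)
  start <- as.integer(unlist(lapply(n, function(k) {
    if (k == 0L) integer() else (seq_len(k) - 1L) * tile_size
  })))
  grid <- data.frame(chrom = chrom, start = start,
                     end = start + as.integer(tile_size),
                     stringsAsFactors = FALSE)
  grid$tile_id <- if (nrow(grid)) {
    paste0(grid$chrom, ":", grid$start, "-", grid$end)
  } else character()
  attr(grid, "tile_size") <- as.integer(tile_size)
  grid
}

#' Coverage-weighted tile methylation for one sample
#'
#' Per tile, over CpGs with `total >= min_cov_per_cpg`:
#' value = sum(meth) / sum(total); `cpg_count` = number of contributing
#' CpGs. Tiles with no contributing CpG are `NA` (missing, not zero).
#'
#' @param calls a [cpg_calls] table.
#' @param tiles grid from [build_tile_grid()].
#' @param min_cov_per_cpg minimum reads for a CpG to contribute (default 3).
#' @return list with numeric `values` and integer `cpg_count`, both aligned
#'   to `tiles`.
#' @export
tile_methylation <- function(calls, tiles, min_cov_per_cpg = 3L) {
  ts <- attr(tiles, "tile_size")
  keep <- calls$total >= min_cov_per_cpg
  values <- rep(NA_real_, nrow(tiles))
  cpg_count <- integer(nrow(tiles))
  if (any(keep)) {
    key <- paste0(calls$chrom[keep], ":", (calls$pos[keep] %/% ts) * ts)
    idx <- match(key, paste0(tiles$chrom, ":", tiles$start))
    ok <- !is.na(idx)   # CpGs in a dropped partial tile contribute nowhere
    if (any(ok)) {
      meth <- rowsum(as.numeric(calls$meth[keep][ok]), idx[ok])
      total <- rowsum(as.numeric(calls$total[keep][ok]), idx[ok])
      cnt <- rowsum(rep(1L, sum(ok)), idx[ok])
      at <- as.integer(rownames(meth))
      values[at] <- meth[, 1L] / total[, 1L]
      cpg_count[at] <- as.integer(cnt[, 1L])
    }
  }
  list(values = values, cpg_count = cpg_count)
}

#' Tile x sample methylation matrix for a cohort
#'
#' @param calls_list named list of [cpg_calls], one per sample.
#' @param tiles grid from [build_tile_grid()].
#' @param min_cov_per_cpg per-CpG coverage filter.
#' @return a `tile_matrix`: list with `tiles`, `values` (tiles x samples,
#'   `NA` = missing), `cpg_count` (tiles x samples) and `tile_size`.
#' @export
tile_matrix <- function(calls_list, tiles, min_cov_per_cpg = 3L) {
  stopifnot(length(calls_list) > 0L, !is.null(names(calls_list)))
  values <- matrix(NA_real_, nrow(tiles), length(calls_list),
                   dimnames = list(tiles$tile_id, names(calls_list)))
  cpg_count <- matrix(0L, nrow(tiles), length(calls_list),
                      dimnames = dimnames(values))
  for (s in seq_along(calls_list)) {
    col <- tile_methylation(calls_list[[s]], tiles, min_cov_per_cpg)
    values[, s] <- col$values
    cpg_count[, s] <- col$cpg_count
  }
  structure(list(tiles = tiles, values = values, cpg_count = cpg_count,
                 tile_size = attr(tiles, "tile_size")),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat(sprintf("<tile_matrix> %d tiles x %d columns (%d bp tiles)\n",
              nrow(x$values), ncol(x$values), x$tile_size))
  invisible(x)
}

#' Population-mean tile matrix
#'
#' Collapses replicate samples to population (tissue x lineage x CD69)
#' means: per tile, the unweighted mean of the replicate tile values
#' (pooled samples count as one replicate); population `cpg_count` is the
#' minimum over replicates. In `strict` mode the population value is
#' missing if any replicate is missing; in `lenient` mode only if all are.
#'
#' @param tm a [tile_matrix()].
#' @param sheet a [sample_sheet] covering every column of `tm`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return a `tile_matrix` whose columns are populations.
#' @export
population_means <- function(tm, sheet, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  samples <- colnames(tm$values)
  if (!all(samples %in% sheet$sample_id)) {
    stop("tile matrix contains samples absent from the sample sheet")
  }
  key <- population_key(sheet)[match(samples, sheet$sample_id)]
  pops <- unique(key)
  values <- matrix(NA_real_, nrow(tm$values), length(pops),
                   dimnames = list(rownames(tm$values), pops))
  cpg_count <- matrix(0L, nrow(tm$values), length(pops),
                      dimnames = dimnames(values))
  for (p in seq_along(pops)) {
    cols <- which(key == pops[p])
    if (!length(cols)) stop("population with zero samples")
    v <- tm$values[, cols, drop = FALSE]
    if (mode == "strict") {
      ok <- rowSums(is.na(v)) == 0L
      values[ok, p] <- rowMeans(v[ok, , drop = FALSE])
    } else {
      any_ok <- rowSums(!is.na(v)) > 0L
      values[any_ok, p] <- rowMeans(v[any_ok, , drop = FALSE], na.rm = TRUE)
    }
    cpg_count[, p] <- apply(tm$cpg_count[, cols, drop = FALSE], 1L, min)
  }
  structure(list(tiles = tm$tiles, values = values, cpg_count = cpg_count,
                 tile_size = tm$tile_size),
            class = "tile_matrix")
}

#' Pairwise DMR call between two populations
#'
#' A tile is reported iff both population values are present, both
#' population CpG counts are `>= min_cpgs`, and the absolute difference of
#' the means is `>= delta`. The signed difference is `meanA - meanB`.
#'
#' @param pop a population [tile_matrix()] (from [population_means()]).
#' @param pop_a,pop_b population column names.
#' @param min_cpgs minimum covered CpGs per tile in each population
#'   (default 5).
#' @param delta minimum absolute methylation difference (default 0.15).
#' @return data frame `tile_id`, `chrom`, `start`, `end`, `diff` of passing
#'   tiles, in genomic order.
#' @export
call_dmrs_pairwise <- function(pop, pop_a, pop_b, min_cpgs = 5L, delta = 0.15) {
  stopifnot(inherits(pop, "tile_matrix"))
  if (!all(c(pop_a, pop_b) %in% colnames(pop$values))) {
    stop("unknown population column")
  }
  a <- pop$values[, pop_a]; b <- pop$values[, pop_b]
  ca <- pop$cpg_count[, pop_a]; cb <- pop$cpg_count[, pop_b]
  d <- a - b
  ## tolerance keeps exact-boundary ratios (e.g. 0.15) from float misses
  pass <- !is.na(d) & ca >= min_cpgs & cb >= min_cpgs &
    abs(d) >= delta - 1e-9
  out <- pop$tiles[pass, c("tile_id", "chrom", "start", "end"), drop = FALSE]
  out$diff <- d[pass]
  rownames(out) <- NULL
  out
}

#' Compile a tissue-specific DMR set from all pairwise calls
#'
#' Union of tiles passing in at least one pairwise comparison within one
#' lineage x CD69 subset, with per-pair signed differences,
#' `max_abs_diff` (largest absolute difference over passing pairs) and the
#' list of passing pairs per tile, in deterministic genomic order.
#'
#' @param pairwise named list of results of [call_dmrs_pairwise()]; names
#'   are `"A|B"` pair keys.
#' @param tiles the tile grid the calls were made on.
#' @param subset optional list (`lineage`, `cd69`) describing the subset.
#' @return a `dmr_set`: list with `tiles` (data frame + `max_abs_diff`),
#'   `pair_diffs` (tiles x pairs, `NA` where not passing), `passing`
#'   (list of pair keys per tile) and `subset`.
#' @export
compile_dmr_set <- function(pairwise, tiles, subset = NULL) {
  stopifnot(is.list(pairwise))
  if (is.null(names(pairwise)) && length(pairwise)) {
    stop("pairwise results must be named by pair key")
  }
  ids <- unique(unlist(lapply(pairwise, `[[`, "tile_id")))
  ord <- match(ids, tiles$tile_id)
  if (anyNA(ord)) stop("pairwise results refer to tiles outside the grid")
  ids <- ids[order(ord)]
  sel <- tiles[match(ids, tiles$tile_id),
               c("tile_id", "chrom", "start", "end"), drop = FALSE]
  rownames(sel) <- NULL
  pair_diffs <- matrix(NA_real_, length(ids), length(pairwise),
                       dimnames = list(ids, names(pairwise)))
  for (k in seq_along(pairwise)) {
    pw <- pairwise[[k]]
    pair_diffs[match(pw$tile_id, ids), k] <- pw$diff
  }
  sel$max_abs_diff <- if (length(ids)) {
    apply(abs(pair_diffs), 1L, max, na.rm = TRUE)
  } else numeric()
  passing <- lapply(seq_along(ids), function(i) {
    names(pairwise)[!is.na(pair_diffs[i, ])]
  })
  structure(list(tiles = sel, pair_diffs = pair_diffs, passing = passing,
                 subset = subset,
                 tile_size = attr(tiles, "tile_size")),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  sub <- if (is.null(x$subset)) "" else {
    sprintf(" [%s %s]", x$subset$lineage, x$subset$cd69)
  }
  cat(sprintf("<dmr_set>%s %d DMRs over %d pairwise comparison(s)\n",
              sub, nrow(x$tiles), ncol(x$pair_diffs)))
  invisible(x)
}

#' Number of DMRs in a set
#' @param set a `dmr_set`.
#' @return integer count.
#' @export
n_dmrs <- function(set) nrow(set$tiles)

#' Call and compile DMRs for one lineage x CD69 subset
#'
#' Convenience wrapper: runs [call_dmrs_pairwise()] for every unordered
#' tissue pair present in the subset and compiles the union.
#'
#' @param tm a sample-level [tile_matrix()].
#' @param sheet the [sample_sheet].
#' @param lineage,cd69 subset selectors.
#' @param tissues tissues to compare (default: all in the subset).
#' @param min_cpgs,delta DMR rule parameters.
#' @param mode replicate aggregation mode, see [population_means()].
#' @return a `dmr_set`.
#' @export
compile_subset_dmrs <- function(tm, sheet, lineage, cd69, tissues = NULL,
                                min_cpgs = 5L, delta = 0.15,
                                mode = "strict") {
  sub <- sheet[sheet$lineage == lineage & sheet$cd69 == cd69, , drop = FALSE]
  if (!nrow(sub)) stop("no samples in the requested subset")
  if (is.null(tissues)) tissues <- unique(sub$tissue)
  cols <- intersect(colnames(tm$values), sub$sample_id)
  stm <- structure(list(tiles = tm$tiles,
                        values = tm$values[, cols, drop = FALSE],
                        cpg_count = tm$cpg_count[, cols, drop = FALSE],
                        tile_size = tm$tile_size), class = "tile_matrix")
  pop <- population_means(stm, sub, mode = mode)
  keys <- paste(tissues, lineage, cd69, sep = ".")
  keys <- keys[keys %in% colnames(pop$values)]
  pairs <- utils::combn(keys, 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) {
    call_dmrs_pairwise(pop, p[1L], p[2L], min_cpgs = min_cpgs, delta = delta)
  })
  names(pairwise) <- vapply(pairs, paste, "", collapse = "|")
  compile_dmr_set(pairwise, tm$tiles,
                  subset = list(lineage = lineage, cd69 = cd69))
}

#' Top-decile DMRs by compiled effect size
#'
#' Keeps DMRs whose `max_abs_diff` is at or above the 90th percentile of
#' the set (ties at the cutoff included).
#'
#' @param set a nonempty `dmr_set`.
#' @return the filtered `dmr_set`.
#' @export
top_decile_dmrs <- function(set) {
  if (n_dmrs(set) == 0L) stop("empty DMR set")
  cut <- stats::quantile(set$tiles$max_abs_diff, 0.9, names = FALSE)
  keep <- set$tiles$max_abs_diff >= cut
  subset_dmr_set(set, keep)
}

#' Subset a DMR set by a logical or integer index
#' @param set a `dmr_set`.
#' @param keep logical or integer index over DMRs.
#' @return the subset `dmr_set`.
#' @export
subset_dmr_set <- function(set, keep) {
  tiles <- set$tiles[keep, , drop = FALSE]
  rownames(tiles) <- NULL
  structure(list(tiles = tiles,
                 pair_diffs = set$pair_diffs[keep, , drop = FALSE],
                 passing = set$passing[keep],
                 subset = set$subset, tile_size = set$tile_size),
            class = "dmr_set")
}

#' Fraction of the genome covered by a DMR set
#' @param set a `dmr_set`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @return total DMR bp / total genome bp.
#' @export
genome_fraction <- function(set, chrom_lengths) {
  if (n_dmrs(set) == 0L) return(0)
  sum(set$tiles$end - set$tiles$start) / sum(as.numeric(chrom_lengths))
}

#' Convert a DMR set to a BED-exportable interval set
#'
#' Scores are `round(1000 * max_abs_diff)`.
#'
#' @param set a `dmr_set`.
#' @return an [interval_set].
#' @export
dmrs_as_intervals <- function(set) {
  interval_set(set$tiles$chrom, set$tiles$start, set$tiles$end,
               label = set$tiles$tile_id,
               score = as.integer(round(1000 * set$tiles$max_abs_diff)),
               name = "dmrs")
}

#' Write the per-pair signed differences of a DMR set as TSV
#' @param set a `dmr_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(set, path) {
  out <- cbind(set$tiles, as.data.frame(set$pair_diffs))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a tile matrix to the tiles of a DMR set
#' @param tm a [tile_matrix()].
#' @param set a `dmr_set` on the same grid.
#' @return a `tile_matrix` over the DMR tiles only.
#' @export
tm_restrict <- function(tm, set) {
  idx <- match(set$tiles$tile_id, tm$tiles$tile_id)
  if (anyNA(idx)) stop("DMR set refers to tiles outside the matrix grid")
  structure(list(tiles = tm$tiles[idx, , drop = FALSE],
                 values = tm$values[idx, , drop = FALSE],
                 cpg_count = tm$cpg_count[idx, , drop = FALSE],
                 tile_size = tm$tile_size),
            class = "tile_matrix")
}
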