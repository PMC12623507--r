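## Synthetic RRBS cohorts with planted ground truth.
##
## The generator emulates the sampling design of a multi-tissue memory T
## cell methylome atlas: a shared CpG landscape, fragment-wise RRBS capture
## of ~40% of CpGs, negative-binomial read depth, a bimodal-plus-intermediate
## baseline methylation landscape coherent within 500 bp tiles, planted
## tile-aligned tissue-specific DMRs, per-donor random offsets, donor pooling
## before sequencing, and PMD blocks whose mean methylation is set per
## tissue group.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.clamp <- function(x, lo = 0.01, hi = 0.99) pmin(hi, pmax(lo, x))

#' Configuration for a synthetic methylome cohort
#'
#' Defaults describe the study conditions the package is validated under:
#' six tissues, three individual donors per population, ~100 bp mean CpG
#' spacing, RRBS capture of 40% of CpGs, 30x mean coverage, 500 bp planted
#' DMRs with a 0.4 methylation difference, small donor effects, and a
#' handful of multi-kilobase PMDs with tissue-shifted mean methylation.
#'
#' @param seed integer RNG seed; all cohort randomness flows from it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param cpg_spacing_mean mean CpG spacing in bp (exponential gaps).
#' @param capture_fraction fraction of CpGs captured by RRBS; capture is
#'   fragment-wise (contiguous CpG runs captured as units, shared across the
#'   cohort), mirroring restriction-fragment capture.
#' @param fragment_cpgs_mean mean CpGs per capturable fragment.
#' @param coverage_mean,coverage_dispersion negative-binomial read depth
#'   (mean and size parameter) per captured CpG.
#' @param baseline_mix baseline methylation mixture: list with `weights`,
#'   `shape1`, `shape2`, each length 3 (low / intermediate / high states);
#'   one state and one Beta-drawn mean are assigned per 500 bp tile so tiles
#'   are internally coherent.
#' @param tissues tissue codes; the last is treated as blood-like only by
#'   the caller, the generator is symmetric in tissues.
#' @param lineages,cd69_states lineage and CD69 strata to simulate (each
#'   tissue x lineage x cd69 combination becomes one population).
#' @param donors_per_tissue individual-donor replicates per population;
#'   scalar or named per-tissue vector (e.g. more blood replicates).
#' @param pooled_per_tissue pooled samples per population (each pooling
#'   `pooled_pool_size` additional donors before "sequencing").
#' @param pooled_pool_size donors per pool.
#' @param n_planted_dmrs number of planted tissue-specific DMR tiles.
#' @param dmr_width planted DMR width (one tile).
#' @param dmr_delta planted methylation difference in \[0, 1\].
#' @param donor_sd SD of per-donor offsets (one offset per donor per
#'   baseline state class).
#' @param pmd_count,pmd_len_range number and bp length range of PMD blocks.
#' @param pmd_level_by_group named per-tissue mean methylation inside PMDs;
#'   `NULL` spreads levels evenly over \[0.5, 0.7\].
#' @param tile_size grid the planted DMRs are aligned to.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                       cpg_spacing_mean = 100,
                       capture_fraction = 0.4,
                       fragment_cpgs_mean = 10,
                       coverage_mean = 30,
                       coverage_dispersion = 5,
                       baseline_mix = list(
                         weights = c(low = 0.25, mid = 0.15, high = 0.60),
                         shape1 = c(low = 1.5, mid = 10, high = 12),
                         shape2 = c(low = 15, mid = 10, high = 2)
                       ),
                       tissues = c("Bm", "In", "Sp", "Lu", "Sk", "Bl"),
                       lineages = "CD4",
                       cd69_states = "pos",
                       donors_per_tissue = 3L,
                       pooled_per_tissue = 0L,
                       pooled_pool_size = 3L,
                       n_planted_dmrs = 200L,
                       dmr_width = 500L,
                       dmr_delta = 0.4,
                       donor_sd = 0.02,
                       pmd_count = 10L,
                       pmd_len_range = c(10000L, 30000L),
                       pmd_level_by_group = NULL,
                       tile_size = 500L) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (capture_fraction < 0 || capture_fraction > 1) {
    stop("capture_fraction must lie in [0, 1]")
  }
  if (dmr_delta < 0 || dmr_delta > 1) stop("dmr_delta must lie in [0, 1]")
  if (any(chrom_lengths < dmr_width)) {
    stop("every chromosome must be at least dmr_width long")
  }
  if (dmr_width != tile_size) {
    stop("planted DMRs are single tiles: dmr_width must equal tile_size")
  }
  if (is.null(pmd_level_by_group)) {
    pmd_level_by_group <- stats::setNames(
      seq(0.5, 0.7, length.out = length(tissues)), tissues)
  }
  if (!all(tissues %in% names(pmd_level_by_group))) {
    stop("pmd_level_by_group must cover every tissue")
  }
  if (length(donors_per_tissue) == 1L && is.null(names(donors_per_tissue))) {
    donors_per_tissue <- stats::setNames(
      rep(as.integer(donors_per_tissue), length(tissues)), tissues)
  }
  if (!all(tissues %in% names(donors_per_tissue))) {
    stop("donors_per_tissue must cover every tissue")
  }
  cfg <- list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    cpg_spacing_mean = cpg_spacing_mean,
    capture_fraction = capture_fraction,
    fragment_cpgs_mean = fragment_cpgs_mean,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    baseline_mix = baseline_mix, tissues = tissues, lineages = lineages,
    cd69_states = cd69_states, donors_per_tissue = donors_per_tissue,
    pooled_per_tissue = as.integer(pooled_per_tissue),
    pooled_pool_size = as.integer(pooled_pool_size),
    n_planted_dmrs = as.integer(n_planted_dmrs),
    dmr_width = as.integer(dmr_width), dmr_delta = dmr_delta,
    donor_sd = donor_sd, pmd_count = as.integer(pmd_count),
    pmd_len_range = as.integer(pmd_len_range),
    pmd_level_by_group = pmd_level_by_group,
    tile_size = as.integer(tile_size)
  )
  class(cfg) <- "sim_config"
  cfg
}

## shared CpG landscape: positions, fragment-wise capture, tile-coherent
## baseline states, PMD membership
.sim_landscape <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  pos_list <- lapply(chroms, function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n_guess <- ceiling(len / cfg$cpg_spacing_mean * 1.3) + 50L
    gaps <- pmax(2L, round(stats::rexp(n_guess, 1 / cfg$cpg_spacing_mean)))
    p <- cumsum(gaps)
    p[p < len]
  })
  names(pos_list) <- chroms
  land <- data.frame(
    chrom = rep(chroms, lengths(pos_list)),
    pos = as.integer(unlist(pos_list)),
    stringsAsFactors = FALSE
  )
  n <- nrow(land)
  land$tile <- paste0(land$chrom, ":", (land$pos %/% cfg$tile_size))

  ## fragment-wise capture filling a CpG quota
  frag_len <- pmax(1L, stats::rpois(n, cfg$fragment_cpgs_mean))
  frag_id <- rep.int(seq_along(frag_len), frag_len)[seq_len(n)]
  frags <- unique(frag_id)
  quota <- round(cfg$capture_fraction * n)
  ord <- sample(frags)
  sizes <- tabulate(frag_id)[ord]
  take <- ord[cumsum(sizes) <= quota]
  # top up with one more fragment if the quota is not yet reached
  if (sum(sizes[seq_along(take)]) < quota && length(take) < length(ord)) {
    take <- c(take, ord[length(take) + 1L])
  }
  land$captured <- frag_id %in% take

  ## baseline state and mean per tile
  tiles <- unique(land$tile)
  mix <- cfg$baseline_mix
  st <- sample(c("low", "mid", "high"), length(tiles), replace = TRUE,
               prob = mix$weights)
  mu <- stats::rbeta(length(tiles), mix$shape1[st], mix$shape2[st])
  idx <- match(land$tile, tiles)
  land$state <- st[idx]
  land$base_mu <- mu[idx]
  land
}

## place non-overlapping tile-aligned PMD blocks
.sim_pmds <- function(cfg) {
  if (cfg$pmd_count == 0L) {
    return(interval_set(character(), integer(), integer(), name = "pmd"))
  }
  ts <- cfg$tile_size
  chroms <- names(cfg$chrom_lengths)
  out <- list(); used <- list()
  attempts <- 0L
  while (length(out) < cfg$pmd_count && attempts < 1000L) {
    attempts <- attempts + 1L
    ch <- sample(chroms, 1L)
    len <- ts * max(1L, round(stats::runif(
      1L, cfg$pmd_len_range[1L], cfg$pmd_len_range[2L]) / ts))
    max_start <- cfg$chrom_lengths[[ch]] - len
    if (max_start < 0) next
    s <- ts * (sample.int(max_start %/% ts + 1L, 1L) - 1L)
    clash <- any(vapply(used, function(u) {
      u$chrom == ch && s < u$end && (s + len) > u$start
    }, logical(1)))
    if (clash) next
    used[[length(used) + 1L]] <- list(chrom = ch, start = s, end = s + len)
    out[[length(out) + 1L]] <- c(ch, s, s + len)
  }
  if (length(out) < cfg$pmd_count) stop("could not place all PMDs; shrink pmd_len_range")
  m <- do.call(rbind, out)
  interval_set(m[, 1L], as.integer(m[, 2L]), as.integer(m[, 3L]),
               label = paste0("PMD_", seq_len(nrow(m))), name = "pmd")
}

.in_intervals <- function(chrom, pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) {
    hit <- hit | (chrom == iv$chrom[i] & pos >= iv$start[i] & pos < iv$end[i])
  }
  hit
}

## choose ascertainable tiles (fully captured, >= min_cpgs CpGs, outside
## PMDs) and plant one DMR per chosen tile
.sim_plant_dmrs <- function(cfg, land, pmds) {
  ts <- cfg$tile_size
  in_pmd <- .in_intervals(land$chrom, land$pos, pmds)
  cap_by_tile <- tapply(land$captured & !in_pmd, land$tile, all)
  n_by_tile <- tapply(land$pos, land$tile, length)
  cand <- names(cap_by_tile)[cap_by_tile & n_by_tile >= 5L]
  if (length(cand) < cfg$n_planted_dmrs) {
    stop(sprintf("only %d ascertainable tiles for %d planted DMRs",
                 length(cand), cfg$n_planted_dmrs))
  }
  chosen <- sample(cand, cfg$n_planted_dmrs)
  parts <- strsplit(chosen, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L)) * ts
  base_mu <- land$base_mu[match(chosen, land$tile)]
  ## direction keeps the shifted level inside [0.01, 0.99]
  can_hypo <- base_mu - cfg$dmr_delta >= 0.01
  can_hyper <- base_mu + cfg$dmr_delta <= 0.99
  if (any(!can_hypo & !can_hyper)) {
    stop("dmr_delta infeasible for some baseline levels; lower dmr_delta")
  }
  direction <- ifelse(can_hypo & (!can_hyper | base_mu >= 0.5), "hypo", "hyper")
  tissue <- rep_len(sample(cfg$tissues), cfg$n_planted_dmrs)
  data.frame(
    chrom = chrom, start = start, end = start + ts,
    tile = chosen, tissue = tissue, direction = direction,
    delta = cfg$dmr_delta, base_mu = base_mu, stringsAsFactors = FALSE
  )
}

## gene models anchored to planted DMRs: even-indexed DMRs get a gene whose
## promoter covers them, odd-indexed ones a gene whose first intron does
.sim_genes <- function(cfg, planted) {
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    ch <- planted$chrom[i]
    s <- planted$start[i]; e <- planted$end[i]
    len <- cfg$chrom_lengths[[ch]]
    mid <- s + (e - s) %/% 2L
    if (i %% 2L == 0L) {
      ## promoter gene: TSS at the DMR midpoint, + strand
      g_start <- mid; g_end <- mid + 4000L
      if (g_end > len) { g_start <- mid - 4000L; g_end <- mid }
      if (g_start < 0L) next
      if (g_start == mid) {
        ex <- .blocks(c(g_start, g_start + 1500L), c(g_start + 400L, g_end))
        strand <- "+"
      } else {
        ex <- .blocks(c(g_start, g_end - 400L), c(g_start + 2500L, g_end))
        strand <- "-"
      }
      rel <- "promoter"
    } else {
      ## intron gene: exons flank the DMR so the DMR sits in intron 1
      g_start <- s - 1500L; g_end <- e + 1500L
      if (g_start < 0L || g_end > len) next
      ex <- .blocks(c(g_start, e + 1000L), c(s - 1000L, g_end))
      strand <- "+"
      rel <- "intron"
    }
    utr5 <- .clip_blocks(ex, ex[1L, 1L], ex[1L, 1L] + 100L)
    utr3 <- .clip_blocks(ex, ex[nrow(ex), 2L] - 100L, ex[nrow(ex), 2L])
    rows[[length(rows) + 1L]] <- list(
      gene_id = sprintf("G%04d", i), chrom = ch, strand = strand,
      start = g_start, end = g_end, exons = ex, utr5 = utr5, utr3 = utr3,
      dmr_index = i, relation = rel
    )
  }
  if (!length(rows)) {
    gm <- data.frame(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(), end = integer())
    gm$exons <- list(); gm$utr5 <- list(); gm$utr3 <- list()
    return(list(genes = gene_model(gm),
                map = data.frame(gene_id = character(), dmr_index = integer())))
  }
  gm <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, function(r) as.integer(r$start), 1L),
    end = vapply(rows, function(r) as.integer(r$end), 1L),
    stringsAsFactors = FALSE
  )
  gm$exons <- lapply(rows, `[[`, "exons")
  gm$utr5 <- lapply(rows, `[[`, "utr5")
  gm$utr3 <- lapply(rows, `[[`, "utr3")
  map <- data.frame(
    gene_id = gm$gene_id,
    dmr_index = vapply(rows, function(r) as.integer(r$dmr_index), 1L),
    relation = vapply(rows, `[[`, "", "relation"),
    stringsAsFactors = FALSE
  )
  list(genes = gene_model(gm), map = map)
}

#' Simulate a cohort of synthetic RRBS methylomes with planted truth
#'
#' Draws one shared CpG landscape, plants tissue-specific DMRs and PMD
#' blocks, then generates per-sample call tables: for each donor the true
#' methylation of a CpG is its tile baseline, plus the planted delta if the
#' CpG lies in a DMR of the sample's tissue, plus the donor's offset for the
#' CpG's baseline state class, clamped to \[0.01, 0.99\]; inside a PMD the
#' true methylation is the tissue's PMD level. Pooled samples average the
#' true methylation of their pool members before read sampling. Observed
#' counts are Binomial(total, mu) with negative-binomial totals, restricted
#' to RRBS-captured CpGs. Identical seeds give identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @return list with `calls` (named list of [cpg_calls]), `sheet`
#'   ([sample_sheet]), `genes` ([gene_model]), `truth` (planted DMRs, donor
#'   effects, PMD set and levels, per-CpG baseline, per-sample true DMR
#'   methylation, DMR-to-gene map) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    land <- .sim_landscape(cfg)
    pmds <- .sim_pmds(cfg)
    planted <- if (cfg$n_planted_dmrs > 0L) {
      .sim_plant_dmrs(cfg, land, pmds)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 tile = character(), tissue = character(),
                 direction = character(), delta = numeric(),
                 base_mu = numeric(), stringsAsFactors = FALSE)
    }
    gene_out <- .sim_genes(cfg, planted)
    in_pmd <- .in_intervals(land$chrom, land$pos, pmds)
    land$in_pmd <- in_pmd

    ## map CpGs to planted DMRs
    dmr_of_cpg <- match(land$tile, planted$tile)

    ## sample sheet: individual donors then pools, per population
    pops <- expand.grid(tissue = cfg$tissues, lineage = cfg$lineages,
                        cd69 = cfg$cd69_states, stringsAsFactors = FALSE)
    sheet_rows <- list(); donor_registry <- character()
    for (p in seq_len(nrow(pops))) {
      t <- pops$tissue[p]; lg <- pops$lineage[p]; cd <- pops$cd69[p]
      n_ind <- cfg$donors_per_tissue[[t]]
      for (r in seq_len(n_ind)) {
        d <- sprintf("D.%s.%s.%s.%d", t, lg, cd, r)
        donor_registry <- c(donor_registry, d)
        sheet_rows[[length(sheet_rows) + 1L]] <- list(
          sample_id = sprintf("%s.%s.%s.ind%d", t, lg, cd, r),
          tissue = t, lineage = lg, cd69 = cd, donors = d)
      }
      if (cfg$pooled_per_tissue > 0L) {
        for (r in seq_len(cfg$pooled_per_tissue)) {
          ds <- sprintf("P.%s.%s.%s.%d.%d", t, lg, cd, r,
                        seq_len(cfg$pooled_pool_size))
          donor_registry <- c(donor_registry, ds)
          sheet_rows[[length(sheet_rows) + 1L]] <- list(
            sample_id = sprintf("%s.%s.%s.pool%d", t, lg, cd, r),
            tissue = t, lineage = lg, cd69 = cd, donors = ds)
        }
      }
    }
    sheet <- sample_sheet(
      sample_id = vapply(sheet_rows, `[[`, "", "sample_id"),
      tissue = vapply(sheet_rows, `[[`, "", "tissue"),
      lineage = vapply(sheet_rows, `[[`, "", "lineage"),
      cd69 = vapply(sheet_rows, `[[`, "", "cd69"),
      donors = lapply(sheet_rows, `[[`, "donors")
    )

    ## one offset per donor per baseline state class
    classes <- c("low", "mid", "high")
    donor_eff <- matrix(stats::rnorm(length(donor_registry) * 3L, 0, cfg$donor_sd),
                        nrow = length(donor_registry), ncol = 3L,
                        dimnames = list(donor_registry, classes))

    cap <- which(land$captured)
    n_cap <- length(cap)
    state_idx <- match(land$state, classes)
    pmd_level <- cfg$pmd_level_by_group

    true_mu_sample <- function(tissue, donors) {
      mus <- vapply(donors, function(d) {
        mu <- land$base_mu + donor_eff[d, ][state_idx]
        k <- which(!is.na(dmr_of_cpg))
        if (length(k)) {
          pd <- planted[dmr_of_cpg[k], ]
          hit <- pd$tissue == tissue
          sgn <- ifelse(pd$direction == "hypo", -1, 1)
          mu[k] <- mu[k] + ifelse(hit, sgn * pd$delta, 0)
        }
        mu <- .clamp(mu)
        mu[land$in_pmd] <- .clamp(pmd_level[[tissue]])
        mu
      }, numeric(nrow(land)))
      rowMeans(mus)
    }

    calls <- vector("list", nrow(sheet))
    names(calls) <- sheet$sample_id
    dmr_true <- matrix(NA_real_, nrow = nrow(planted), ncol = nrow(sheet),
                       dimnames = list(planted$tile, sheet$sample_id))
    for (s in seq_len(nrow(sheet))) {
      mu <- true_mu_sample(sheet$tissue[s], sheet$donors[[s]])
      total <- stats::rnbinom(n_cap, size = cfg$coverage_dispersion,
                              mu = cfg$coverage_mean)
      keep <- total > 0L
      meth <- stats::rbinom(sum(keep), total[keep], mu[cap][keep])
      calls[[s]] <- cpg_calls(
        chrom = land$chrom[cap][keep], pos = land$pos[cap][keep],
        meth = meth, total = total[keep], sample_id = sheet$sample_id[s]
      )
      if (nrow(planted)) {
        dmr_true[, s] <- vapply(seq_len(nrow(planted)), function(i) {
          mean(mu[which(dmr_of_cpg == i)])
        }, numeric(1))
      }
    }

    truth <- list(
      planted_dmrs = planted,
      donor_effects = donor_eff,
      pmd_intervals = pmds,
      pmd_level_by_group = pmd_level,
      baseline = land,
      dmr_true_meth = dmr_true,
      dmr_gene_map = gene_out$map
    )
    list(calls = calls, sheet = sheet, genes = gene_out$genes,
         truth = truth, config = cfg)
  })
}

#' Simulate per-gene expression coupled to planted DMR methylation
#'
#' For each gene anchored to a planted DMR, expression of sample `s` is
#' `a + b * (1 - m_s) + N(0, noise_sd)`, where `m_s` is the sample's true
#' regional methylation of the DMR. Positive `b` yields the canonical
#' negative methylation-expression correlation. Units mimic linear-scale
#' counts per million.
#'
#' @param truth the `truth` component of [simulate_cohort()].
#' @param a baseline expression.
#' @param b methylation coupling (expression units per unit demethylation).
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return matrix genes x samples of linear-scale expression.
#' @export
simulate_expression <- function(truth, a = 5, b = 50, noise_sd = 5, seed = 1L) {
  map <- truth$dmr_gene_map
  if (nrow(map) == 0L) stop("no genes are anchored to planted DMRs")
  m <- truth$dmr_true_meth[map$dmr_index, , drop = FALSE]
  .with_seed(seed, {
    expr <- a + b * (1 - m) +
      matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
    dimnames(expr) <- list(map$gene_id, colnames(m))
    expr
  })
}

#' Write all cohort artifacts to a directory
#'
#' Emits one bismark-coverage file per sample, the sample sheet, the planted
#' DMR and PMD BED tracks, a planted-truth TSV and a JSON echo of the
#' resolved configuration.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$calls)) {
    write_cpg_calls(cohort$calls[[s]],
                    file.path(dir, "calls", paste0(s, ".cov")))
  }
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  pd <- cohort$truth$planted_dmrs
  if (nrow(pd)) {
    write_intervals(
      interval_set(pd$chrom, pd$start, pd$end,
                   label = paste0(pd$tissue, "_", pd$direction),
                   name = "planted_dmrs"),
      file.path(dir, "planted_dmrs.bed"))
  }
  write_intervals(cohort$truth$pmd_intervals, file.path(dir, "pmds.bed"))
  utils::write.table(
    pd[, c("chrom", "start", "end", "tissue", "direction", "delta")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
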