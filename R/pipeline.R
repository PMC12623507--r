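## Pipeline front-end: validated configuration, independently re-runnable
## stages over on-disk artifacts, and a manifest. A thin command-line
## wrapper lives in inst/cli/tmethatlas.R.

#' Pipeline configuration
#'
#' Paths and parameters for the staged pipeline. Defaults follow the
#' analysis conventions of the package: 500 bp tiles, >= 5 covered CpGs and
#' a 15 percentage-point difference for a DMR, >= 3 reads per CpG, TSS
#' +/- 3 kb promoters, top 3000 genes.
#'
#' @param outdir output directory.
#' @param calls_dir directory of per-sample bismark coverage files (filled
#'   by the `simulate` stage when absent).
#' @param sample_sheet,genes,pmds paths to the sample sheet TSV, gene BED12
#'   and PMD BED (filled by `simulate` when absent).
#' @param tile_size,min_cpgs,delta,min_cov_per_cpg DMR-rule parameters.
#' @param tss_flank,n_top_genes annotation parameters.
#' @param pca_components,manova_k,n_clusters multivariate parameters
#'   (`pca_components = NULL`: all available).
#' @param seed integer seed driving all randomness.
#' @param sim a [sim_config()] used by the `simulate` stage (its seed is
#'   overridden by `seed`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            calls_dir = file.path(outdir, "cohort", "calls"),
                            sample_sheet = file.path(outdir, "cohort", "sample_sheet.tsv"),
                            genes = file.path(outdir, "cohort", "genes.bed"),
                            pmds = file.path(outdir, "cohort", "pmds.bed"),
                            tile_size = 500L, min_cpgs = 5L, delta = 0.15,
                            min_cov_per_cpg = 3L, tss_flank = 3000L,
                            n_top_genes = 3000L, pca_components = NULL,
                            manova_k = 2L, n_clusters = NULL, seed = 1L,
                            sim = sim_config()) {
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  for (v in c(tile_size, min_cpgs, min_cov_per_cpg, tss_flank, n_top_genes,
              manova_k)) {
    if (v <= 0) stop("all thresholds must be positive")
  }
  sim$seed <- as.integer(seed)
  structure(list(
    outdir = outdir, calls_dir = calls_dir, sample_sheet = sample_sheet,
    genes = genes, pmds = pmds, tile_size = as.integer(tile_size),
    min_cpgs = as.integer(min_cpgs), delta = delta,
    min_cov_per_cpg = as.integer(min_cov_per_cpg),
    tss_flank = as.integer(tss_flank), n_top_genes = as.integer(n_top_genes),
    pca_components = pca_components, manova_k = as.integer(manova_k),
    n_clusters = n_clusters, seed = as.integer(seed), sim = sim
  ), class = "pipeline_config")
}

#' Read the per-pair DMR table written by [write_dmr_table()]
#' @param path TSV path.
#' @param tile_size tile width (default 500).
#' @return a `dmr_set`.
#' @export
read_dmr_table <- function(path, tile_size = 500L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("tile_id", "chrom", "start", "end", "max_abs_diff")
  pair_cols <- setdiff(names(df), fixed)
  pair_diffs <- as.matrix(df[, pair_cols, drop = FALSE])
  rownames(pair_diffs) <- df$tile_id
  structure(list(
    tiles = df[, fixed, drop = FALSE],
    pair_diffs = pair_diffs,
    passing = lapply(seq_len(nrow(df)), function(i) {
      pair_cols[!is.na(pair_diffs[i, ])]
    }),
    subset = NULL, tile_size = as.integer(tile_size)
  ), class = "dmr_set")
}

#' Write gene models as BED12
#'
#' The thick (CDS) span is the transcript minus the annotated UTRs, so UTRs
#' survive a round-trip through [read_gene_models()].
#'
#' @param gm a [gene_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  lines <- vapply(seq_len(nrow(gm)), function(i) {
    ex <- gm$exons[[i]]
    u5 <- gm$utr5[[i]]; u3 <- gm$utr3[[i]]
    left <- if (gm$strand[i] == "+") u5 else u3
    right <- if (gm$strand[i] == "+") u3 else u5
    thick_s <- if (NROW(left)) max(left[, 2L]) else gm$start[i]
    thick_e <- if (NROW(right)) min(right[, 1L]) else gm$end[i]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            gm$chrom[i], gm$start[i], gm$end[i], gm$gene_id[i],
            gm$strand[i], thick_s, thick_e, nrow(ex),
            paste0(ex[, 2L] - ex[, 1L], collapse = ","),
            paste0(ex[, 1L] - gm$start[i], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tile matrix as TSV (percent scale, 1 decimal)
#' @param tm a [tile_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tile_matrix <- function(tm, path) {
  pct <- round(100 * tm$values, 1L)
  out <- data.frame(tile_id = tm$tiles$tile_id, pct,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_cohort <- function(cfg) {
  files <- sort(list.files(cfg$calls_dir, pattern = "\\.cov$",
                           full.names = TRUE))
  if (!length(files)) stop("no .cov files under ", cfg$calls_dir)
  calls <- lapply(files, read_cpg_calls, format = "bismark_cov")
  names(calls) <- vapply(calls, sample_id, "")
  sheet <- read_sample_sheet(cfg$sample_sheet)
  list(calls = calls, sheet = sheet)
}

.chrom_lengths_from_calls <- function(calls, tile_size) {
  pos <- do.call(rbind, lapply(calls, function(x) {
    as.data.frame(x)[, c("chrom", "pos")]
  }))
  mx <- tapply(pos$pos, pos$chrom, max)
  ## round the observed span up to whole tiles
  stats::setNames(as.integer((mx %/% tile_size + 1L) * tile_size), names(mx))
}

.subsets_of <- function(sheet) {
  unique(sheet[, c("lineage", "cd69")])
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic cohort + truth + expression), `tile`
#' (tile matrix TSV), `dmr` (per-subset compiled DMR sets), `pmd`
#' (PMD methylation table), `pca` (scores, donor variance, MANOVA),
#' `cluster` (regulatory-DMR heatmap clustering), `annotate` (feature flags,
#' composition, gene ranking), `assoc` (rank tests and
#' methylation-expression regression), or `all`. Later stages read earlier
#' stages' on-disk artifacts, so each stage can be re-run independently.
#' A manifest JSON (inputs, parameter echo, seed, artifacts) is written per
#' invocation.
#'
#' @param stage one of the stage names above.
#' @param cfg a [pipeline_config()].
#' @return path to the manifest, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "tile", "dmr", "pmd",
                                   "pca", "cluster", "annotate", "assoc"),
                         cfg) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "tile", "dmr", "pmd", "pca", "cluster", "annotate", "assoc")
  } else stage
  artifacts <- character()
  log_stage <- function(name) {
    message(sprintf("[tmethatlas] stage %s (%s)", name, format(Sys.time(), "%T")))
  }
  for (st in stages) {
    log_stage(st)
    artifacts <- c(artifacts, switch(st,
      simulate = .stage_simulate(cfg),
      tile = .stage_tile(cfg),
      dmr = .stage_dmr(cfg),
      pmd = .stage_pmd(cfg),
      pca = .stage_pca(cfg),
      cluster = .stage_cluster(cfg),
      annotate = .stage_annotate(cfg),
      assoc = .stage_assoc(cfg)
    ))
  }
  manifest <- list(
    package = "tmethatlas",
    version = as.character(utils::packageVersion("tmethatlas")),
    stage = stage, seed = cfg$seed,
    parameters = cfg[c("tile_size", "min_cpgs", "delta", "min_cov_per_cpg",
                       "tss_flank", "n_top_genes", "manova_k")],
    inputs = cfg[c("calls_dir", "sample_sheet", "genes", "pmds")],
    artifacts = sub(paste0("^", cfg$outdir, "/?"), "", artifacts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  mp <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

.stage_simulate <- function(cfg) {
  cohort <- simulate_cohort(cfg$sim)
  cdir <- file.path(cfg$outdir, "cohort")
  write_cohort(cohort, cdir)
  write_gene_models(cohort$genes, file.path(cdir, "genes.bed"))
  expr <- simulate_expression(cohort$truth, seed = cfg$seed + 1L)
  utils::write.table(
    data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
    file.path(cdir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  file.path(cdir, c("sample_sheet.tsv", "genes.bed", "pmds.bed",
                    "truth.tsv", "expression.tsv", "config.json"))
}

.tile_matrix_from_disk <- function(cfg) {
  co <- .read_cohort(cfg)
  lens <- .chrom_lengths_from_calls(co$calls, cfg$tile_size)
  tiles <- build_tile_grid(lens, cfg$tile_size)
  tm <- tile_matrix(co$calls, tiles, cfg$min_cov_per_cpg)
  list(tm = tm, sheet = co$sheet, calls = co$calls, lens = lens)
}

.stage_tile <- function(cfg) {
  d <- .tile_matrix_from_disk(cfg)
  p <- file.path(cfg$outdir, "tile_matrix.tsv")
  write_tile_matrix(d$tm, p)
  p
}

.stage_dmr <- function(cfg) {
  d <- .tile_matrix_from_disk(cfg)
  out <- character()
  subs <- .subsets_of(d$sheet)
  for (i in seq_len(nrow(subs))) {
    set <- compile_subset_dmrs(d$tm, d$sheet, subs$lineage[i], subs$cd69[i],
                               min_cpgs = cfg$min_cpgs, delta = cfg$delta)
    tag <- paste0(subs$lineage[i], "_", subs$cd69[i])
    bed <- file.path(cfg$outdir, sprintf("dmrs_%s.bed", tag))
    tsv <- file.path(cfg$outdir, sprintf("dmrs_%s.tsv", tag))
    write_intervals(dmrs_as_intervals(set), bed)
    write_dmr_table(set, tsv)
    out <- c(out, bed, tsv)
  }
  out
}

.first_subset_tag <- function(sheet) {
  subs <- .subsets_of(sheet)
  paste0(subs$lineage[1L], "_", subs$cd69[1L])
}

.stage_pmd <- function(cfg) {
  co <- .read_cohort(cfg)
  pmds <- read_intervals(cfg$pmds, name = "pmd")
  p <- file.path(cfg$outdir, "pmd_methylation.tsv")
  if (nrow(pmds) == 0L) {
    utils::write.table(
      data.frame(sample_id = character(), pmd_id = character(),
                 meth_pct = numeric(), n_cpgs = integer()),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    return(p)
  }
  tab <- pmd_cohort_table(co$calls, pmds, cfg$min_cov_per_cpg)
  tab$meth_pct <- round(tab$meth_pct, 4L)
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

.dmr_sample_matrix <- function(cfg) {
  d <- .tile_matrix_from_disk(cfg)
  tag <- .first_subset_tag(d$sheet)
  set <- read_dmr_table(file.path(cfg$outdir, sprintf("dmrs_%s.tsv", tag)),
                        cfg$tile_size)
  sub <- d$sheet[d$sheet$lineage == .subsets_of(d$sheet)$lineage[1L] &
                   d$sheet$cd69 == .subsets_of(d$sheet)$cd69[1L], ,
                 drop = FALSE]
  tm <- tm_restrict(d$tm, set)
  mat <- tm$values[, sub$sample_id, drop = FALSE]
  list(mat = impute_row_means(mat), sheet = sub, set = set, tag = tag,
       lens = d$lens)
}

.stage_pca <- function(cfg) {
  d <- .dmr_sample_matrix(cfg)
  fit <- pca_fit(d$mat, k = cfg$pca_components)
  sc <- file.path(cfg$outdir, "pca_scores.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(fit$scores), fit$scores,
               check.names = FALSE),
    sc, sep = "\t", quote = FALSE, row.names = FALSE)
  dv <- donor_variance(d$mat)
  dvp <- file.path(cfg$outdir, "donor_variance.tsv")
  utils::write.table(dv, dvp, sep = "\t", quote = FALSE, row.names = FALSE)
  tissue <- d$sheet$tissue[match(rownames(fit$scores), d$sheet$sample_id)]
  mv <- manova_tissue(fit$scores, tissue,
                      k = min(cfg$manova_k, ncol(fit$scores)))
  mvp <- file.path(cfg$outdir, "manova.json")
  jsonlite::write_json(unclass(mv), mvp, auto_unbox = TRUE, digits = NA)
  c(sc, dvp, mvp)
}

.stage_cluster <- function(cfg) {
  d <- .dmr_sample_matrix(cfg)
  genes <- read_gene_models(cfg$genes, "bed12")
  ann <- annotate_dmrs(d$set, genes, cfg$tss_flank)
  reg <- filter_regulatory(ann)
  keep <- match(reg$tiles$tile_id, rownames(d$mat))
  mat <- zscore_rows(d$mat[keep, , drop = FALSE])
  k <- if (is.null(cfg$n_clusters)) length(unique(d$sheet$tissue)) else cfg$n_clusters
  cl <- hcluster(mat, "columns", n_clusters = k)
  p <- file.path(cfg$outdir, "cluster_labels.tsv")
  utils::write.table(
    data.frame(sample_id = names(cl$labels), cluster = cl$labels,
               leaf_order = order(cl$order)[seq_along(cl$labels)]),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

.stage_annotate <- function(cfg) {
  d <- .dmr_sample_matrix(cfg)
  genes <- read_gene_models(cfg$genes, "bed12")
  ann <- annotate_dmrs(d$set, genes, cfg$tss_flank)
  ap <- file.path(cfg$outdir, "dmr_annotation.tsv")
  flags <- apply(ann$flags, 1L, function(f) {
    paste(colnames(ann$flags)[f], collapse = ",")
  })
  utils::write.table(
    data.frame(tile_id = rownames(ann$flags), flags = flags,
               stringsAsFactors = FALSE),
    ap, sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- feature_composition(ann)
  cp <- file.path(cfg$outdir, "feature_composition.tsv")
  utils::write.table(
    data.frame(feature = names(comp), fraction = as.numeric(comp)),
    cp, sep = "\t", quote = FALSE, row.names = FALSE)
  gl <- file.path(cfg$outdir, "gene_list.txt")
  write_gene_list(rank_genes(ann, cfg$n_top_genes), gl)
  gf <- genome_fraction(d$set, d$lens)
  gfp <- file.path(cfg$outdir, "genome_fraction.json")
  jsonlite::write_json(list(genome_fraction = gf), gfp, auto_unbox = TRUE,
                       digits = NA)
  c(ap, cp, gl, gfp)
}

.stage_assoc <- function(cfg) {
  d <- .dmr_sample_matrix(cfg)
  out <- character()
  ## rank tests on the strongest DMRs, every tissue vs the reference
  ord <- order(-d$set$tiles$max_abs_diff)
  top <- utils::head(ord, 5L)
  rows <- lapply(top, function(i) {
    v <- split(d$mat[i, ], d$sheet$tissue[match(colnames(d$mat),
                                                d$sheet$sample_id)])
    cc <- compare_groups(v, mode = "vs_reference")
    cbind(tile_id = d$set$tiles$tile_id[i], as.data.frame(cc))
  })
  gp <- file.path(cfg$outdir, "group_comparisons.tsv")
  utils::write.table(do.call(rbind, rows), gp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(out, gp)
  ## methylation-expression regression where expression is available
  ep <- file.path(cfg$outdir, "cohort", "expression.tsv")
  if (file.exists(ep)) {
    expr <- utils::read.table(ep, sep = "\t", header = TRUE,
                              check.names = FALSE)
    genes <- read_gene_models(cfg$genes, "bed12")
    ann <- annotate_dmrs(d$set, genes, cfg$tss_flank)
    g <- ann$genes[ann$genes$relation %in% c("promoter", "intron"), ]
    g <- g[g$gene_id %in% expr$gene_id, , drop = FALSE]
    g <- g[!duplicated(g$gene_id), , drop = FALSE]
    res <- lapply(seq_len(nrow(g)), function(j) {
      m <- d$mat[match(g$tile_id[j], rownames(d$mat)), ]
      e <- as.numeric(expr[match(g$gene_id[j], expr$gene_id),
                           colnames(d$mat)])
      if (anyNA(e) || stats::var(m) == 0) return(NULL)
      r <- regress_meth_expr(m, e)
      data.frame(gene_id = g$gene_id[j], tile_id = g$tile_id[j],
                 slope = r$slope, r_squared = r$r_squared, p = r$p, n = r$n,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    rp <- file.path(cfg$outdir, "meth_expr_regression.tsv")
    utils::write.table(res, rp, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, rp)
  }
  out
}
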