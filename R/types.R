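#' Construct a per-sample CpG call table
#'
#' The atomic methylome: one row per CpG with methylated and total read
#' counts. Coordinates are 0-based positions of the CpG cytosine; calls are
#' assumed strand-merged (destranded), so there is one record per CpG site.
#' Methylation at a site is the fraction `meth / total`; sites without
#' coverage are simply absent (absence, never zero, encodes missingness).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based CpG positions.
#' @param meth integer vector of methylated read counts.
#' @param total integer vector of total read counts (> 0).
#' @param sample_id single string identifying the sample.
#' @return A `cpg_calls` data frame with columns `chrom`, `pos`, `meth`,
#'   `total`, sorted by chromosome then position, carrying a `sample_id`
#'   attribute.
#' @export
cpg_calls <- function(chrom, pos, meth, total, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    meth = as.integer(meth),
    total = as.integer(total),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$pos < 0L)) stop("CpG positions must be non-negative")
    if (any(df$total <= 0L)) stop("total read count must be positive")
    if (any(df$meth < 0L) || any(df$meth > df$total)) {
      stop("meth_count must lie in [0, total_count]")
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    dup <- unlist(tapply(df$pos, df$chrom, function(p) duplicated(p)))
    if (any(dup)) stop("duplicate CpG positions within a chromosome")
    rownames(df) <- NULL
  }
  attr(df, "sample_id") <- sample_id
  class(df) <- c("cpg_calls", "data.frame")
  df
}

#' @export
print.cpg_calls <- function(x, ...) {
  cat(sprintf(
    "<cpg_calls> sample '%s': %d CpGs on %d chromosome(s)\n",
    sample_id(x), nrow(x), length(unique(x$chrom))
  ))
  invisible(x)
}

#' Sample identifier of a CpG call table
#' @param x a `cpg_calls` object.
#' @return the sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Construct a named set of genomic intervals
#'
#' Holds DMR or PMD intervals in 0-based half-open coordinates with an
#' optional BED score in \[0, 1000\] and a label per interval.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param label optional labels (default `name` + running index).
#' @param score optional integer scores in \[0, 1000\] (default 0).
#' @param name set name (single string).
#' @return An `interval_set` data frame with columns `chrom`, `start`,
#'   `end`, `label`, `score`.
#' @export
interval_set <- function(chrom, start, end, label = NULL, score = NULL,
                         name = "intervals") {
  n <- length(chrom)
  if (is.null(label)) label <- if (n) paste0(name, "_", seq_len(n)) else character()
  if (is.null(score)) score <- rep(0L, n)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    label = as.character(label),
    score = as.integer(score),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0L)) stop("interval starts must be non-negative")
    if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
    if (any(df$score < 0L | df$score > 1000L)) stop("scores must lie in [0, 1000]")
  }
  attr(df, "name") <- name
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "<interval_set> '%s': %d interval(s), %s bp total\n",
    attr(x, "name"), nrow(x), format(sum(x$end - x$start), big.mark = ",")
  ))
  invisible(x)
}

## exon/utr blocks are 2-column integer matrices (start, end), half-open
.blocks <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Construct a gene model (one transcript per gene)
#'
#' @param genes a data frame with columns `gene_id`, `chrom`,
#'   `strand` (`+`/`-`), `start`, `end` (transcript span, 0-based
#'   half-open) and list columns `exons`, `utr5`, `utr3`, each entry a
#'   2-column matrix of half-open intervals (possibly 0-row). The TSS is
#'   derived from the strand: transcript start on `+`, `end - 1` on `-`.
#' @return A `gene_model` data frame with a derived `tss` column; introns
#'   are the gaps between consecutive exons (see [gene_introns()]).
#' @export
gene_model <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exons", "utr5", "utr3")
  stopifnot(all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0L) stop("each gene needs at least one exon")
    if (any(ex[, 1L] >= ex[, 2L])) stop("exon start must be < end")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
      stop(sprintf("overlapping exons in gene '%s'", genes$gene_id[i]))
    }
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  class(genes) <- c("gene_model", "data.frame")
  genes
}

#' Intron intervals of each gene
#' @param gm a `gene_model`.
#' @return list (per gene) of 2-column matrices of intron intervals.
#' @export
gene_introns <- function(gm) {
  lapply(gm$exons, function(ex) {
    if (nrow(ex) < 2L) return(.blocks(integer(), integer()))
    .blocks(ex[-nrow(ex), 2L], ex[-1L, 1L])
  })
}

#' Construct a sample sheet
#'
#' Maps each methylome to its tissue, lineage, CD69 status and donor(s).
#' Pooled samples (several donors pooled before sequencing) carry all
#' contributing donor ids; `pooled` is derived as `length(donors) > 1`.
#'
#' @param sample_id character vector, unique.
#' @param tissue tissue codes (e.g. Bm, In, Sp, Lu, Sk, Bl).
#' @param lineage `"CD4"` or `"CD8"`.
#' @param cd69 `"pos"` or `"neg"`.
#' @param donors list of character vectors of donor ids (or a character
#'   vector of semicolon-separated ids).
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, tissue, lineage, cd69, donors) {
  if (is.character(donors)) donors <- strsplit(donors, ";", fixed = TRUE)
  stopifnot(is.list(donors))
  if (anyDuplicated(sample_id)) stop("sample_id must be unique")
  if (!all(lineage %in% c("CD4", "CD8"))) stop("lineage must be CD4 or CD8")
  if (!all(cd69 %in% c("pos", "neg"))) stop("cd69 must be 'pos' or 'neg'")
  df <- data.frame(
    sample_id = as.character(sample_id),
    tissue = as.character(tissue),
    lineage = as.character(lineage),
    cd69 = as.character(cd69),
    stringsAsFactors = FALSE
  )
  df$donors <- lapply(donors, as.character)
  df$pooled <- vapply(df$donors, function(d) length(d) > 1L, logical(1))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Population key (tissue.lineage.cd69) per sample
#' @param sheet a `sample_sheet`.
#' @return character vector of population keys.
#' @export
population_key <- function(sheet) {
  paste(sheet$tissue, sheet$lineage, sheet$cd69, sep = ".")
}
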