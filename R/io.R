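## File formats. Internal convention everywhere: 0-based half-open
## coordinates; methylation as a fraction in [0, 1]. 1-based coordinates and
## percent scales exist only at the bismark/bedGraph boundary.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' Read a per-sample CpG call table
#'
#' Supports the Bismark coverage dialect (tab-separated: chrom, start
#' (1-based), end (1-based inclusive), percent methylation, methylated
#' count, unmethylated count) and a counts bedGraph dialect (chrom, start
#' (0-based), end (half-open), methylated count, total count). The percent
#' column of bismark files is ignored; counts are authoritative.
#'
#' @param path file path.
#' @param format `"bismark_cov"` or `"bedgraph_counts"`.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return a [cpg_calls] table (0-based positions, sorted).
#' @export
read_cpg_calls <- function(path, format = c("bismark_cov", "bedgraph_counts"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(cov|txt|tsv|bedgraph|bedGraph)(\\.gz)?$", "",
                     basename(path))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(cpg_calls(character(), integer(), integer(), integer(), sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (format == "bismark_cov") 6L else 5L
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d tab-separated fields, got %d",
                 path, bad[1L], want, nf[bad[1L]]))
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  chrom <- m[, 1L]
  if (format == "bismark_cov") {
    pos <- suppressWarnings(as.integer(m[, 2L])) - 1L   # 1-based -> 0-based
    meth <- suppressWarnings(as.integer(m[, 5L]))
    unmeth <- suppressWarnings(as.integer(m[, 6L]))
    total <- meth + unmeth
  } else {
    pos <- suppressWarnings(as.integer(m[, 2L]))
    meth <- suppressWarnings(as.integer(m[, 4L]))
    total <- suppressWarnings(as.integer(m[, 5L]))
  }
  bad <- which(is.na(pos) | is.na(meth) | is.na(total))
  if (length(bad)) stop(sprintf("%s line %d: malformed numeric field", path, bad[1L]))
  bad <- which(meth > total)
  if (length(bad)) {
    stop(sprintf("%s line %d: methylated count exceeds total", path, bad[1L]))
  }
  cpg_calls(chrom, pos, meth, total, sample_id)
}

#' Write a CpG call table
#'
#' @param calls a [cpg_calls] table.
#' @param path output path.
#' @param format `"bismark_cov"` (1-based, percent + meth/unmeth counts) or
#'   `"bedgraph_counts"` (0-based half-open, meth/total counts).
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path,
                            format = c("bismark_cov", "bedgraph_counts")) {
  format <- match.arg(format)
  if (format == "bismark_cov") {
    pct <- ifelse(calls$total > 0L, 100 * calls$meth / calls$total, 0)
    out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   calls$chrom, calls$pos + 1L, calls$pos + 1L,
                   format(pct, trim = TRUE, digits = 7),
                   calls$meth, calls$total - calls$meth)
  } else {
    out <- sprintf("%s\t%d\t%d\t%d\t%d",
                   calls$chrom, calls$pos, calls$pos + 1L,
                   calls$meth, calls$total)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an interval set as BED6
#'
#' Lines are `chrom start end label score .` (0-based half-open, strand
#' unused). Round-trips through [read_intervals()].
#'
#' @param x an [interval_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  out <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                 x$chrom, x$start, x$end, x$label, x$score)
  writeLines(out, path)
  invisible(path)
}

#' Read a BED file into an interval set
#'
#' Accepts BED3 to BED6; missing label/score columns are defaulted.
#'
#' @param path BED file path.
#' @param name set name.
#' @return an [interval_set].
#' @export
read_intervals <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L || !length(readLines(path, n = 1L))) {
    return(interval_set(character(), integer(), integer(), name = name))
  }
  df <- .read_tsv(path)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  interval_set(
    chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
    label = if (ncol(df) >= 4L) df[[4L]] else NULL,
    score = if (ncol(df) >= 5L) df[[5L]] else NULL,
    name = name
  )
}

.parse_block_list <- function(sizes, starts, chrom_start) {
  sz <- as.integer(strsplit(sizes, ",", fixed = TRUE)[[1L]])
  st <- as.integer(strsplit(starts, ",", fixed = TRUE)[[1L]])
  .blocks(chrom_start + st, chrom_start + st + sz)
}

#' Read gene models
#'
#' `bed12`: standard BED12; exons from blockSizes/blockStarts, UTRs derived
#' from thickStart/thickEnd (the CDS span) intersected with exons. `gtf_min`:
#' a minimal GTF with `exon`, and optionally `five_prime_utr` /
#' `three_prime_utr`, features carrying a `gene_id "..."` attribute; gene
#' span is the exon envelope.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gtf_min"`.
#' @return a [gene_model] (one transcript per gene; strand-aware TSS).
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf_min")) {
  format <- match.arg(format)
  df <- .read_tsv(path)
  if (format == "bed12") {
    if (ncol(df) < 12L) stop("BED12 requires 12 columns")
    n <- nrow(df)
    exons <- vector("list", n); utr5 <- vector("list", n); utr3 <- vector("list", n)
    for (i in seq_len(n)) {
      ex <- .parse_block_list(df[i, 11L], df[i, 12L], as.integer(df[i, 2L]))
      exons[[i]] <- ex
      thick_s <- as.integer(df[i, 7L]); thick_e <- as.integer(df[i, 8L])
      left <- .clip_blocks(ex, as.integer(df[i, 2L]), thick_s)
      right <- .clip_blocks(ex, thick_e, as.integer(df[i, 3L]))
      if (df[i, 6L] == "+") { utr5[[i]] <- left; utr3[[i]] <- right }
      else { utr5[[i]] <- right; utr3[[i]] <- left }
    }
    gm <- data.frame(
      gene_id = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
      strand = as.character(df[[6L]]),
      start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
      stringsAsFactors = FALSE
    )
    gm$exons <- exons; gm$utr5 <- utr5; gm$utr3 <- utr3
    return(gene_model(gm))
  }
  ## minimal GTF: 1-based inclusive coordinates in columns 4-5
  if (ncol(df) < 9L) stop("GTF requires 9 columns")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", df[[9L]])
  if (any(gid == df[[9L]])) stop("GTF attribute column lacks gene_id on some lines")
  feats <- split(seq_len(nrow(df)), gid)
  rows <- lapply(names(feats), function(g) {
    idx <- feats[[g]]
    sub <- df[idx, , drop = FALSE]
    strand <- unique(sub[[7L]])
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop(sprintf("gene '%s': missing or inconsistent strand", g))
    }
    pick <- function(type) {
      s <- sub[sub[[3L]] == type, , drop = FALSE]
      .blocks(as.integer(s[[4L]]) - 1L, as.integer(s[[5L]]))
    }
    ex <- pick("exon")
    if (nrow(ex) == 0L) stop(sprintf("gene '%s': no exon features", g))
    list(gene_id = g, chrom = as.character(sub[1L, 1L]), strand = strand,
         start = min(ex[, 1L]), end = max(ex[, 2L]),
         exons = ex, utr5 = pick("five_prime_utr"), utr3 = pick("three_prime_utr"))
  })
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
  gene_model(gm)
}

## intersect exon blocks with [lo, hi)
.clip_blocks <- function(blocks, lo, hi) {
  if (hi <= lo || nrow(blocks) == 0L) return(.blocks(integer(), integer()))
  s <- pmax(blocks[, 1L], lo); e <- pmin(blocks[, 2L], hi)
  keep <- s < e
  .blocks(s[keep], e[keep])
}

#' Read a sample sheet TSV
#'
#' Header columns: `sample_id`, `tissue`, `lineage`, `cd69`, `donors`
#' (semicolon-separated donor ids), `pooled` (ignored on input; re-derived
#' from the donor list).
#'
#' @param path TSV path.
#' @return a [sample_sheet].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "lineage", "cd69", "donors")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  sample_sheet(df$sample_id, df$tissue, df$lineage, df$cd69, df$donors)
}

#' Write a sample sheet TSV
#' @param sheet a [sample_sheet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- data.frame(
    sample_id = sheet$sample_id, tissue = sheet$tissue,
    lineage = sheet$lineage, cd69 = sheet$cd69,
    donors = vapply(sheet$donors, paste, "", collapse = ";"),
    pooled = sheet$pooled, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a browser methylation track (bedGraph, percent scale)
#'
#' Four columns: chrom, start, end (0-based half-open single-CpG spans) and
#' percent methylation on a 0-100 scale.
#'
#' @param calls a [cpg_calls] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(calls, path) {
  pct <- 100 * calls$meth / calls$total
  writeLines(sprintf("%s\t%d\t%d\t%.1f", calls$chrom, calls$pos,
                     calls$pos + 1L, pct), path)
  invisible(path)
}
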