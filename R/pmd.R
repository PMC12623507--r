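## Weighted methylation over partially methylated domains (PMDs).
## PMD intervals are an input (previously reported domains), never
## discovered here.

#' Weighted average methylation over PMD intervals
#'
#' Per PMD: sum(meth) / sum(total) over covered CpGs inside the interval
#' (coverage-weighted); PMDs with no contributing CpG are `NA`. The global
#' value aggregates raw counts over all PMDs, so it is invariant to how the
#' domains are partitioned into sub-intervals.
#'
#' @param calls a [cpg_calls] table.
#' @param pmds an [interval_set] of non-overlapping PMD intervals.
#' @param min_cov_per_cpg minimum reads for a CpG to contribute (default 3).
#' @return a `pmd_profile`: list with `sample_id`, `per_pmd` (data frame
#'   `label`, `chrom`, `start`, `end`, `meth`, `n_cpgs`) and
#'   `global_pmd_meth`.
#' @export
pmd_weighted_methylation <- function(calls, pmds, min_cov_per_cpg = 3L) {
  stopifnot(inherits(pmds, "interval_set"))
  if (nrow(pmds) > 1L) {
    gr <- GenomicRanges::GRanges(pmds$chrom,
                                 IRanges::IRanges(pmds$start + 1L, pmds$end))
    if (sum(IRanges::width(GenomicRanges::reduce(gr))) <
        sum(IRanges::width(gr))) {
      stop("PMD intervals overlap; merge them before use")
    }
  }
  keep <- calls$total >= min_cov_per_cpg
  meth_sum <- numeric(nrow(pmds))
  total_sum <- numeric(nrow(pmds))
  n_cpgs <- integer(nrow(pmds))
  if (any(keep) && nrow(pmds)) {
    cg <- GenomicRanges::GRanges(
      calls$chrom[keep],
      IRanges::IRanges(calls$pos[keep] + 1L, calls$pos[keep] + 1L))
    pg <- GenomicRanges::GRanges(pmds$chrom,
                                 IRanges::IRanges(pmds$start + 1L, pmds$end))
    hits <- GenomicRanges::findOverlaps(cg, pg)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(q)) {
      meth_sum <- vapply(seq_len(nrow(pmds)), function(i) {
        sum(calls$meth[keep][q[s == i]])
      }, numeric(1))
      total_sum <- vapply(seq_len(nrow(pmds)), function(i) {
        sum(calls$total[keep][q[s == i]])
      }, numeric(1))
      n_cpgs <- vapply(seq_len(nrow(pmds)), function(i) {
        sum(s == i)
      }, integer(1))
    }
  }
  per <- data.frame(
    label = pmds$label, chrom = pmds$chrom, start = pmds$start,
    end = pmds$end,
    meth = ifelse(n_cpgs > 0L, meth_sum / total_sum, NA_real_),
    n_cpgs = n_cpgs, stringsAsFactors = FALSE
  )
  structure(list(
    sample_id = sample_id(calls),
    per_pmd = per,
    global_pmd_meth = if (sum(total_sum) > 0) {
      sum(meth_sum) / sum(total_sum)
    } else NA_real_,
    n_cpgs_global = sum(n_cpgs),
    total_reads_global = sum(total_sum)
  ), class = "pmd_profile")
}

#' @export
print.pmd_profile <- function(x, ...) {
  cat(sprintf("<pmd_profile> sample '%s': %d PMD(s), global methylation %s\n",
              x$sample_id, nrow(x$per_pmd),
              ifelse(is.na(x$global_pmd_meth), "NA",
                     sprintf("%.3f", x$global_pmd_meth))))
  invisible(x)
}

#' PMD methylation table for a cohort
#'
#' @param calls_list named list of [cpg_calls].
#' @param pmds an [interval_set] of PMDs.
#' @param min_cov_per_cpg per-CpG coverage filter.
#' @return data frame `sample_id`, `pmd_id`, `meth_pct`, `n_cpgs`, with one
#'   extra `GLOBAL` row per sample carrying the count-weighted aggregate.
#' @export
pmd_cohort_table <- function(calls_list, pmds, min_cov_per_cpg = 3L) {
  rows <- lapply(calls_list, function(calls) {
    p <- pmd_weighted_methylation(calls, pmds, min_cov_per_cpg)
    rbind(
      data.frame(sample_id = p$sample_id, pmd_id = p$per_pmd$label,
                 meth_pct = 100 * p$per_pmd$meth,
                 n_cpgs = p$per_pmd$n_cpgs, stringsAsFactors = FALSE),
      data.frame(sample_id = p$sample_id, pmd_id = "GLOBAL",
                 meth_pct = 100 * p$global_pmd_meth,
                 n_cpgs = p$n_cpgs_global, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
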