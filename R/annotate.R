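## Genomic-feature annotation of DMRs.
##
## A DMR may carry several feature flags (promoter, 5'UTR, exon, intron,
## 3'UTR); `intergenic` means no other flag. The promoter is TSS +/- 3 kb in
## strand-oriented coordinates regardless of gene-body overlap.

.FEATURES <- c("promoter", "utr5", "exon", "intron", "utr3")

## strand-oriented +/- flank window around the TSS, genomic half-open
.promoter_window <- function(tss, strand, flank) {
  if (strand == "+") c(tss - flank, tss + flank)
  else c(tss - flank + 1L, tss + flank + 1L)
}

#' Annotate DMRs with genomic features and associated genes
#'
#' Tests each DMR for overlap (any overlap counts) with the promoter window
#' (TSS +/- `tss_flank`, strand-oriented), 5' UTRs, exons, introns (gaps
#' between consecutive exons) and 3' UTRs of every gene. Each overlapping
#' gene is recorded with all applicable relations and the signed,
#' strand-oriented distance from the DMR midpoint to the TSS (negative =
#' upstream of the TSS).
#'
#' @param set a `dmr_set`.
#' @param genes a [gene_model].
#' @param tss_flank promoter half-width in bp (default 3000).
#' @return an `annotated_dmrs`: list with `set`, `flags` (DMRs x 6 logical
#'   matrix incl. `intergenic`) and `genes` (data frame `dmr_idx`,
#'   `tile_id`, `gene_id`, `relation`, `distance_to_tss`).
#' @export
annotate_dmrs <- function(set, genes, tss_flank = 3000L) {
  stopifnot(inherits(set, "dmr_set"), inherits(genes, "gene_model"))
  n <- n_dmrs(set)
  flags <- matrix(FALSE, n, length(.FEATURES) + 1L,
                  dimnames = list(set$tiles$tile_id, c(.FEATURES, "intergenic")))
  hits <- list()
  if (n > 0L && nrow(genes) > 0L) {
    known <- unique(set$tiles$chrom)
    skip <- !(genes$chrom %in% known)
    if (any(skip)) {
      warning(sprintf("skipping %d gene(s) on chromosomes absent from the DMR set",
                      sum(skip)))
      genes <- genes[!skip, , drop = FALSE]
    }
    introns <- gene_introns(genes)
    feat_rows <- list()
    for (i in seq_len(nrow(genes))) {
      add <- function(blocks, feature) {
        if (NROW(blocks) == 0L) return(NULL)
        data.frame(chrom = genes$chrom[i],
                   start = pmax(0L, blocks[, 1L]), end = blocks[, 2L],
                   gene = i, feature = feature, stringsAsFactors = FALSE)
      }
      pw <- .promoter_window(genes$tss[i], genes$strand[i], tss_flank)
      feat_rows[[length(feat_rows) + 1L]] <- do.call(rbind, c(list(
        add(matrix(pw, 1L), "promoter")),
        list(add(genes$utr5[[i]], "utr5"),
             add(genes$exons[[i]], "exon"),
             add(introns[[i]], "intron"),
             add(genes$utr3[[i]], "utr3"))
      ))
    }
    feats <- do.call(rbind, feat_rows)
    feats <- feats[feats$end > feats$start, , drop = FALSE]
    if (nrow(feats)) {
      dg <- GenomicRanges::GRanges(
        set$tiles$chrom,
        IRanges::IRanges(set$tiles$start + 1L, set$tiles$end))
      fg <- GenomicRanges::GRanges(
        feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end))
      ov <- GenomicRanges::findOverlaps(dg, fg)
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      if (length(q)) {
        flags[cbind(q, match(feats$feature[s], colnames(flags)))] <- TRUE
        mid <- set$tiles$start[q] + (set$tiles$end[q] - set$tiles$start[q]) %/% 2L
        gi <- feats$gene[s]
        dist <- ifelse(genes$strand[gi] == "+",
                       mid - genes$tss[gi], genes$tss[gi] - mid)
        hits <- data.frame(
          dmr_idx = q, tile_id = set$tiles$tile_id[q],
          gene_id = genes$gene_id[gi], relation = feats$feature[s],
          distance_to_tss = as.integer(dist), stringsAsFactors = FALSE)
        hits <- unique(hits)
        hits <- hits[order(hits$dmr_idx, hits$gene_id, hits$relation), ,
                     drop = FALSE]
        rownames(hits) <- NULL
      }
    }
  }
  if (!is.data.frame(hits)) {
    hits <- data.frame(dmr_idx = integer(), tile_id = character(),
                       gene_id = character(), relation = character(),
                       distance_to_tss = integer(), stringsAsFactors = FALSE)
  }
  flags[, "intergenic"] <- rowSums(flags[, .FEATURES, drop = FALSE]) == 0L
  structure(list(set = set, flags = flags, genes = hits,
                 tss_flank = as.integer(tss_flank)),
            class = "annotated_dmrs")
}

#' @export
print.annotated_dmrs <- function(x, ...) {
  cat(sprintf("<annotated_dmrs> %d DMRs, %d gene association(s)\n",
              nrow(x$flags), nrow(x$genes)))
  invisible(x)
}

#' Feature composition of an annotated DMR set
#'
#' Per-feature fraction of DMRs carrying that flag (a DMR may carry several
#' flags, so fractions can sum above 1), plus `any_feature`, the fraction
#' with at least one non-intergenic flag, and `regulatory`, the fraction
#' with a promoter or intron flag.
#'
#' @param ann an [annotate_dmrs()] result.
#' @return named numeric vector of fractions.
#' @export
feature_composition <- function(ann) {
  stopifnot(inherits(ann, "annotated_dmrs"))
  n <- nrow(ann$flags)
  if (n == 0L) stop("empty DMR set")
  fr <- colMeans(ann$flags)
  c(fr[.FEATURES], intergenic = unname(fr["intergenic"]),
    any_feature = mean(!ann$flags[, "intergenic"]),
    regulatory = mean(ann$flags[, "promoter"] | ann$flags[, "intron"]))
}

#' Keep only putatively regulatory DMRs
#'
#' Retains DMRs with a promoter flag (TSS +/- 3 kb) or an intron flag,
#' the subset used for signature clustering.
#'
#' @param ann an [annotate_dmrs()] result.
#' @return the filtered `dmr_set`.
#' @export
filter_regulatory <- function(ann) {
  stopifnot(inherits(ann, "annotated_dmrs"))
  keep <- ann$flags[, "promoter"] | ann$flags[, "intron"]
  subset_dmr_set(ann$set, keep)
}

#' Rank genes by their promoter/intron DMR load
#'
#' Gene score: number of associated promoter or intron DMRs, ties broken by
#' the largest compiled `max_abs_diff` among those DMRs, then by gene id.
#' The head of the ranking is the gene list exported for external
#' enrichment tools.
#'
#' @param ann an [annotate_dmrs()] result.
#' @param n genes to return (default 3000).
#' @return data frame `gene_id`, `n_dmrs`, `best_diff` in rank order.
#' @export
rank_genes <- function(ann, n = 3000L) {
  stopifnot(inherits(ann, "annotated_dmrs"))
  if (n <= 0L) stop("n must be positive")
  g <- ann$genes[ann$genes$relation %in% c("promoter", "intron"), , drop = FALSE]
  if (nrow(g) == 0L) {
    return(data.frame(gene_id = character(), n_dmrs = integer(),
                      best_diff = numeric(), stringsAsFactors = FALSE))
  }
  g <- unique(g[, c("gene_id", "dmr_idx")])
  mad <- ann$set$tiles$max_abs_diff[g$dmr_idx]
  counts <- tapply(g$dmr_idx, g$gene_id, length)
  best <- tapply(mad, g$gene_id, max)
  out <- data.frame(gene_id = names(counts),
                    n_dmrs = as.integer(counts),
                    best_diff = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(-out$n_dmrs, -out$best_diff, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Write a one-id-per-line gene list
#' @param ranking result of [rank_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ranking, path) {
  writeLines(ranking$gene_id, path)
  invisible(path)
}
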