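## Multivariate structure of the DMR methylation matrix: donor variance,
## PCA with held-out projection, MANOVA tissue-vs-donor decomposition,
## Z-scoring and hierarchical clustering.

.pop_var <- function(x) mean((x - mean(x))^2)

#' Per-sample variance and CV of methylation across compiled DMRs
#'
#' For each sample (donor), the variance of its methylation values across
#' the compiled tissue-specific DMRs, and the coefficient of variation
#' (sd / mean). Missing tile values are excluded. The population
#' denominator (n) is the default; `denominator = "n-1"` switches to the
#' sample variance.
#'
#' @param mat DMRs x samples methylation matrix (fractions, `NA` allowed).
#' @param denominator `"n"` (default) or `"n-1"`.
#' @return data frame `sample_id`, `n_dmrs`, `variance`, `sd`, `cv`.
#' @export
donor_variance <- function(mat, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  out <- lapply(colnames(mat), function(s) {
    v <- mat[, s]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop(sprintf("sample '%s': fewer than 2 DMR values", s))
    va <- if (denominator == "n") .pop_var(v) else stats::var(v)
    sd <- sqrt(va)
    data.frame(sample_id = s, n_dmrs = length(v), variance = va, sd = sd,
               cv = sd / mean(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean-impute missing entries of a DMR x sample matrix
#'
#' Each missing value is replaced by the row (per-DMR) mean over non-missing
#' samples; rows missing everywhere are dropped with a warning.
#'
#' @param mat DMRs x samples matrix.
#' @return the imputed matrix.
#' @export
impute_row_means <- function(mat) {
  all_na <- rowSums(!is.na(mat)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping %d all-missing row(s)", sum(all_na)))
    mat <- mat[!all_na, , drop = FALSE]
  }
  na_at <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(na_at)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    mat[na_at] <- rm[na_at[, 1L]]
  }
  mat
}

#' Principal component analysis of a DMR x sample matrix
#'
#' Samples are the observations and DMRs the variables: the input is
#' transposed, centred per DMR, not variance-scaled. Signs follow a fixed
#' convention (the largest-magnitude loading of each component is positive)
#' so results are deterministic. Explained-variance ratios are eigenvalues
#' over total variance.
#'
#' @param mat DMRs x samples numeric matrix, no missing values (see
#'   [impute_row_means()]).
#' @param k number of components (default `min(n_samples - 1, n_DMRs)`).
#' @return a `pca_result`: `scores` (samples x k), `loadings` (DMRs x k),
#'   `explained_variance_ratio`, `center` (per-DMR means).
#' @export
pca_fit <- function(mat, k = NULL) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  n <- ncol(mat)
  if (n < 2L) stop("PCA needs at least 2 samples")
  kmax <- min(n - 1L, nrow(mat))
  if (is.null(k)) k <- kmax
  if (k > kmax) stop(sprintf("requested %d components, only %d available", k, kmax))
  x <- t(mat)                              # samples x DMRs
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  ratio <- if (total > 0) ev / total else rep(0, length(ev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = ratio[seq_len(k)],
                 center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d components; PC1 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance_ratio[1L]))
  invisible(x)
}

#' Project held-out samples into a fitted PC space
#'
#' Uses the training centring means and loadings only, so projecting a
#' training sample reproduces its fitted score and projecting the training
#' mean profile lands at the origin.
#'
#' @param fit a [pca_fit()] result.
#' @param mat DMRs x new-samples matrix over the same DMR rows as training.
#' @return new-samples x k score matrix.
#' @export
pca_project <- function(fit, mat) {
  stopifnot(inherits(fit, "pca_result"), is.matrix(mat))
  if (nrow(mat) != nrow(fit$loadings)) {
    stop("row universe differs from the training matrix")
  }
  sweep(t(mat), 2L, fit$center) %*% fit$loadings
}

#' One-way MANOVA of PC scores on tissue
#'
#' Wilks' lambda with Rao's approximate F over the first `k` components.
#' The F statistic is the tissue-to-residual (donor) variance ratio; the
#' residual captures between-donor variation within tissues. For `k = 1`
#' this reduces to the one-way ANOVA F.
#'
#' @param scores samples x components score matrix.
#' @param tissue character/factor tissue label per sample.
#' @param k components to use (default 2).
#' @return a `manova_result`: `statistic_name`, `F`, `p`, `df_between`,
#'   `df_within`, `wilks`.
#' @export
manova_tissue <- function(scores, tissue, k = 2L) {
  stopifnot(is.matrix(scores), nrow(scores) == length(tissue))
  if (k > ncol(scores)) stop("k exceeds available components")
  tissue <- factor(tissue)
  if (nlevels(tissue) < 2L) stop("need at least 2 tissues")
  y <- scores[, seq_len(k), drop = FALSE]
  if (k == 1L) {
    fit <- stats::aov(y[, 1L] ~ tissue)
    tab <- summary(fit)[[1L]]
    res <- list(statistic_name = "Wilks", F = tab$`F value`[1L],
                p = tab$`Pr(>F)`[1L], df_between = tab$Df[1L],
                df_within = tab$Df[2L], wilks = NA_real_)
  } else {
    fit <- tryCatch(stats::manova(y ~ tissue), error = function(e) {
      stop("MANOVA failed: ", conditionMessage(e))
    })
    tab <- tryCatch(summary(fit, test = "Wilks")$stats,
                    error = function(e) {
                      stop("singular within-group covariance: ",
                           conditionMessage(e))
                    })
    res <- list(statistic_name = "Wilks", F = tab[1L, "approx F"],
                p = tab[1L, "Pr(>F)"], df_between = tab[1L, "num Df"],
                df_within = tab[1L, "den Df"], wilks = tab[1L, "Wilks"])
  }
  structure(res, class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("<manova_result> Wilks F = %.3f (df %g, %g), p = %.3g\n",
              x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Z-score each row across samples
#'
#' Each row is standardised to `(x - mean) / sd` using the population sd
#' (denominator n); rows with zero sd become all zeros.
#'
#' @param mat numeric matrix (rows = DMRs, columns = samples).
#' @return the row-standardised matrix.
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat))
  m <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - m)^2))
  out <- (mat - m) / ifelse(s == 0, 1, s)
  out[s == 0, ] <- 0
  out
}

#' Hierarchical clustering of rows or columns
#'
#' Euclidean distance with Ward linkage (`ward.D2`) by default; flat labels
#' by cutting the tree at `n_clusters`. Rows should be Z-scored first when
#' clustering DMRs.
#'
#' @param mat numeric matrix without missing values.
#' @param axis `"rows"` or `"columns"`.
#' @param n_clusters number of flat clusters.
#' @param distance `"euclidean"` (passed to [stats::dist()]).
#' @param linkage linkage method (default `"ward.D2"`).
#' @return a `cluster_result`: `axis`, `tree` (hclust), `labels` (named flat
#'   assignment), `order` (leaf order).
#' @export
hcluster <- function(mat, axis = c("rows", "columns"), n_clusters = 2L,
                     distance = "euclidean", linkage = "ward.D2") {
  axis <- match.arg(axis)
  stopifnot(is.matrix(mat), !anyNA(mat))
  x <- if (axis == "rows") mat else t(mat)
  if (n_clusters > nrow(x)) stop("n_clusters exceeds number of leaves")
  tree <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  labels <- stats::cutree(tree, k = n_clusters)
  structure(list(axis = axis, tree = tree, labels = labels,
                 order = tree$order, n_clusters = n_clusters),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: %d leaves cut into %d cluster(s)\n",
              x$axis, length(x$labels), x$n_clusters))
  invisible(x)
}
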