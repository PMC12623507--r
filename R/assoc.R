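## Locus-level statistics: rank-based comparisons of DMR methylation across
## tissue groups, and simple linear regression of methylation against
## linear-scale gene expression.

#' Significance stars for a p-value
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p numeric p-value(s).
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

.rank_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    ## degenerate: every value identical in both groups
    return(list(U = length(x) * length(y) / 2, p = 1, degenerate = TRUE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value), degenerate = FALSE)
}

#' Rank-based group comparison of one DMR's methylation
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum tests between tissue groups:
#' exact null when the combined n is at most 20 and there are no ties,
#' normal approximation with tie and continuity correction otherwise.
#' `mode = "vs_reference"` (default) tests every tissue against the
#' reference group; `mode = "all"` tests all unordered pairs.
#'
#' @param values named list: tissue -> numeric methylation values.
#' @param mode `"vs_reference"` or `"all"`.
#' @param reference reference tissue for `vs_reference` (default `"Bl"`,
#'   falling back to the first group).
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (default `"none"`, matching raw-star reporting).
#' @return a `group_comparison`: data frame `group_a`, `group_b`, `U`, `p`,
#'   `stars`, `degenerate`.
#' @export
compare_groups <- function(values, mode = c("vs_reference", "all"),
                           reference = "Bl", p_adjust = "none") {
  mode <- match.arg(mode)
  stopifnot(is.list(values), !is.null(names(values)), length(values) >= 2L)
  pairs <- if (mode == "all") {
    utils::combn(names(values), 2L, simplify = FALSE)
  } else {
    if (!reference %in% names(values)) reference <- names(values)[1L]
    lapply(setdiff(names(values), reference), function(g) c(g, reference))
  }
  rows <- lapply(pairs, function(p) {
    x <- values[[p[1L]]]; y <- values[[p[2L]]]
    if (length(x) < 2L || length(y) < 2L) {
      stop(sprintf("pair %s vs %s: need >= 2 values per group", p[1L], p[2L]))
    }
    r <- .rank_test(x, y)
    data.frame(group_a = p[1L], group_b = p[2L], U = r$U, p = r$p,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- p_stars(out$p_adj)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Simple linear regression of expression on DMR methylation
#'
#' Ordinary least squares of linear-scale expression on the methylation
#' fraction; the p-value is the two-sided t-test on the slope.
#'
#' @param meth methylation fractions per sample.
#' @param expr matching linear-scale expression values.
#' @return a `regression_result`: `slope`, `intercept`, `r`, `r_squared`,
#'   `p`, `n`.
#' @export
regress_meth_expr <- function(meth, expr) {
  stopifnot(length(meth) == length(expr))
  ok <- !is.na(meth) & !is.na(expr)
  meth <- meth[ok]; expr <- expr[ok]
  n <- length(meth)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::var(meth) == 0) stop("zero variance in methylation: slope undefined")
  fit <- stats::lm(expr ~ meth)
  sm <- suppressWarnings(summary(fit))  # noiseless fits are a legal input
  slope <- unname(stats::coef(fit)[2L])
  r <- suppressWarnings(stats::cor(meth, expr))
  p <- if (stats::var(expr) == 0) 1 else sm$coefficients[2L, 4L]
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r_squared = r^2, p = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.4g, r^2 %.3f, p %.3g (n = %d)\n",
    x$slope, x$r_squared, x$p, x$n))
  invisible(x)
}
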