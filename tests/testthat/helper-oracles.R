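# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (per-element loops) so they cannot share a defect with
# the vectorised implementations they check.

# random CpG call table
rand_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L,
                       sample_id = "S1") {
  pos_by <- lapply(chroms, function(ch) sort(sample.int(max_pos, n)) - 1L)
  total <- sample(1:40, n * length(chroms), replace = TRUE)
  cpg_calls(
    chrom = rep(chroms, each = n),
    pos = unlist(pos_by),
    meth = vapply(total, function(t) sample.int(t + 1L, 1L) - 1L, 1L),
    total = total, sample_id = sample_id
  )
}

# per-CpG loop oracle for coverage-weighted tile methylation
oracle_tile_meth <- function(calls, tiles, min_cov = 3L) {
  values <- rep(NA_real_, nrow(tiles))
  counts <- integer(nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    m <- 0L; t <- 0L; k <- 0L
    for (j in seq_len(nrow(calls))) {
      if (calls$chrom[j] == tiles$chrom[i] &&
          calls$pos[j] >= tiles$start[i] && calls$pos[j] < tiles$end[i] &&
          calls$total[j] >= min_cov) {
        m <- m + calls$meth[j]; t <- t + calls$total[j]; k <- k + 1L
      }
    }
    if (k > 0L) { values[i] <- m / t; counts[i] <- k }
  }
  list(values = values, cpg_count = counts)
}

# quadratic interval-overlap oracle (0-based half-open)
oracle_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# exact two-sided Mann-Whitney p by exhaustive label enumeration
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  mu <- m * (n - m) / 2
  combos <- utils::combn(n, m)
  us <- apply(combos, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# closed-form OLS slope / intercept / two-sided slope p
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# a 3-gene hand-built model on one chromosome
tiny_gene_model <- function() {
  gm <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(10000L, 40000L, 70000L),
    end = c(16000L, 46000L, 73000L),
    stringsAsFactors = FALSE
  )
  gm$exons <- list(
    .b(c(10000L, 12000L, 15000L), c(10500L, 12800L, 16000L)),
    .b(c(40000L, 44000L), c(41000L, 46000L)),
    .b(70000L, 73000L)
  )
  gm$utr5 <- list(.b(10000L, 10200L), .b(45500L, 46000L), .b(integer(), integer()))
  gm$utr3 <- list(.b(15500L, 16000L), .b(40000L, 40400L), .b(integer(), integer()))
  gene_model(gm)
}

.b <- function(s, e) cbind(start = as.integer(s), end = as.integer(e))

# small cohort used by several test files (no PMDs, clear signal)
small_cohort <- function(seed = 11, ...) {
  simulate_cohort(sim_config(
    seed = seed, chrom_lengths = c(chr1 = 150000L, chr2 = 150000L),
    tissues = c("Bm", "Lu", "Sk"), donors_per_tissue = 3L,
    n_planted_dmrs = 30L, pmd_count = 0L, ...
  ))
}
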