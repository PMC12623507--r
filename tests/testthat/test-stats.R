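test_that("donor variance and CV follow the population formulas", {
  m <- matrix(0.5, nrow = 4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  dv <- donor_variance(m)
  expect_equal(dv$variance, c(0, 0))
  expect_equal(dv$cv, c(0, 0))

  m2 <- matrix(c(0, 1, 0, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
  dv2 <- donor_variance(m2)
  expect_equal(dv2$variance[1], 0.25)
  expect_equal(dv2$cv[1], 1.0)

  set.seed(701)
  m3 <- matrix(runif(500), ncol = 1, dimnames = list(NULL, "s"))
  m3[sample(500, 20), 1] <- NA
  dv3 <- donor_variance(m3)
  v <- m3[!is.na(m3[, 1]), 1]
  # textbook loop oracle
  mu <- sum(v) / length(v)
  ss <- 0
  for (x in v) ss <- ss + (x - mu)^2
  expect_equal(dv3$variance, ss / length(v), tolerance = 1e-12)
  expect_equal(dv3$cv, sqrt(ss / length(v)) / mu, tolerance = 1e-12)
  dvn1 <- donor_variance(m3, denominator = "n-1")
  expect_equal(dvn1$variance, ss / (length(v) - 1), tolerance = 1e-12)
})

test_that("PCA handles degenerate and rank-1 inputs and matches an eigensolve", {
  # two identical samples: zero variance handled without error
  same <- matrix(0.4, nrow = 6, ncol = 2, dimnames = list(NULL, c("a", "b")))
  fit <- pca_fit(same)
  expect_equal(fit$explained_variance_ratio[1], 0)

  # rank-1 matrix: PC1 explains everything
  u <- runif(8)
  r1 <- outer(u, c(1, 2, 3))
  colnames(r1) <- paste0("s", 1:3)
  expect_equal(pca_fit(r1)$explained_variance_ratio[1], 1)

  # oracle: direct eigendecomposition of the sample covariance
  set.seed(702)
  mat <- matrix(runif(20 * 8), nrow = 20, dimnames = list(NULL, paste0("s", 1:8)))
  fit <- pca_fit(mat)
  x <- scale(t(mat), center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  for (j in 1:7) {
    sc_o <- x %*% eg$vectors[, j]
    agree <- min(max(abs(fit$scores[, j] - sc_o)),
                 max(abs(fit$scores[, j] + sc_o)))
    expect_lt(agree, 1e-8)
  }
  expect_equal(fit$explained_variance_ratio[1:7],
               (eg$values / sum(eg$values))[1:7], tolerance = 1e-8)
})

test_that("projection reuses training centering: training rows and mean profile", {
  set.seed(703)
  mat <- matrix(runif(30 * 6), nrow = 30, dimnames = list(NULL, paste0("s", 1:6)))
  fit <- pca_fit(mat, k = 3)
  proj <- pca_project(fit, mat[, 2, drop = FALSE])
  expect_equal(as.numeric(proj), as.numeric(fit$scores[2, ]), tolerance = 1e-10)
  mean_prof <- matrix(rowMeans(mat), ncol = 1)
  expect_equal(max(abs(pca_project(fit, mean_prof))), 0, tolerance = 1e-10)
  expect_error(pca_project(fit, mat[-1, 1, drop = FALSE]), "row universe")
})

test_that("a projected held-out sample lands nearest its generating tissue", {
  co <- small_cohort(seed = 71)
  tiles <- build_tile_grid(co$config$chrom_lengths)
  tm <- tile_matrix(co$calls, tiles)
  set <- compile_subset_dmrs(tm, co$sheet, "CD4", "pos")
  mat <- impute_row_means(tm_restrict(tm, set)$values)
  # hold out one skin sample, fit on the rest
  held <- "Sk.CD4.pos.ind3"
  fit <- pca_fit(mat[, setdiff(colnames(mat), held)], k = 2)
  proj <- pca_project(fit, mat[, held, drop = FALSE])
  tis <- co$sheet$tissue[match(rownames(fit$scores), co$sheet$sample_id)]
  cent <- apply(fit$scores, 2, function(x) tapply(x, tis, mean))
  d <- sqrt(rowSums(sweep(cent, 2, as.numeric(proj))^2))
  expect_equal(names(which.min(d)), "Sk")
})

test_that("MANOVA reduces to the ANOVA F for k = 1 and separates clear groups", {
  # hand-computable 2-tissue case
  y <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("A", "B"), each = 3)
  mv <- manova_tissue(matrix(y, ncol = 1), g, k = 1)
  gm <- mean(y)
  ssb <- 3 * ((2 - gm)^2 + (8 - gm)^2)
  ssw <- sum((y - rep(c(2, 8), each = 3))^2)
  expect_equal(mv$F, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  expect_equal(mv$df_between, 1)
  expect_equal(mv$df_within, 4)

  # near-identical within tissue, distinct between: F huge, p tiny
  set.seed(704)
  sc <- rbind(matrix(rnorm(8, 0, 1e-3), ncol = 2),
              matrix(rnorm(8, 5, 1e-3), ncol = 2),
              matrix(rnorm(8, -5, 1e-3), ncol = 2))
  mv2 <- manova_tissue(sc, rep(c("A", "B", "C"), each = 4), k = 2)
  expect_gt(mv2$F, 1e4)
  expect_lt(mv2$p, 1e-10)
})

test_that("MANOVA F is invariant to constant shifts and sample reordering", {
  set.seed(705)
  sc <- matrix(rnorm(24), ncol = 2)
  g <- rep(c("A", "B", "C"), each = 4)
  f0 <- manova_tissue(sc, g)$F
  expect_equal(manova_tissue(sc + 3.7, g)$F, f0, tolerance = 1e-10)
  perm <- sample(12)
  expect_equal(manova_tissue(sc[perm, ], g[perm])$F, f0, tolerance = 1e-10)
})

test_that("row z-scores use the population sd and zero out constant rows", {
  m <- matrix(c(0.2, 0.4, 0.6, 0.5, 0.5, 0.5), nrow = 2, byrow = TRUE)
  z <- zscore_rows(m)
  expect_equal(z[1, ], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z[2, ], c(0, 0, 0))
  set.seed(706)
  r <- matrix(runif(50 * 7), nrow = 50)
  zr <- zscore_rows(r)
  expect_lt(max(abs(rowMeans(zr))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans(zr^2)) - 1)), 1e-12)
})

test_that("hierarchical clustering separates blobs and is row-order invariant", {
  set.seed(707)
  blob <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 4),
                matrix(rnorm(40, 3, 0.1), ncol = 4))
  cl <- hcluster(blob, "rows", n_clusters = 2)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  expect_equal(length(unique(cl$labels[11:20])), 1L)
  expect_false(cl$labels[1] == cl$labels[11])

  # Ward linkage heights are non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-12))

  # row permutation permutes labels consistently
  perm <- sample(20)
  cl2 <- hcluster(blob[perm, ], "rows", n_clusters = 2)
  agree <- table(cl$labels[perm], cl2$labels)
  expect_equal(sum(agree > 0), 2L)
  expect_error(hcluster(blob, "rows", n_clusters = 21), "leaves")
})

test_that("samples cluster by tissue on a planted cohort", {
  co <- small_cohort(seed = 72)
  tiles <- build_tile_grid(co$config$chrom_lengths)
  tm <- tile_matrix(co$calls, tiles)
  set <- compile_subset_dmrs(tm, co$sheet, "CD4", "pos")
  mat <- zscore_rows(impute_row_means(tm_restrict(tm, set)$values))
  cl <- hcluster(mat, "columns", n_clusters = 3)
  tis <- co$sheet$tissue[match(names(cl$labels), co$sheet$sample_id)]
  purity <- table(cl$labels, tis)
  expect_true(all(rowSums(purity > 0) == 1))
})

test_that("mean imputation fills gaps with per-DMR means and drops dead rows", {
  m <- matrix(c(0.2, NA, 0.4, NA, NA, NA), nrow = 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("a", "b", "c")))
  expect_warning(out <- impute_row_means(m), "all-missing")
  expect_equal(nrow(out), 1L)
  expect_equal(out[1, "b"], 0.3)
})
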