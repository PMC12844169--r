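# Diagnostic battery: RSD, PCA, correlation reports, LOESS, silhouette.

test_that("RSD follows 100 * sd / mean and flags zero-mean features", {
  m <- rbind(c(10, 8, 0), c(10, 10, 0), c(10, 12, 0))
  ds <- make_dataset(m, roles = rep("qc", 3))
  s <- compute_rsd(ds, "qc")
  expect_equal(unname(s$rsd[1]), 0)
  expect_equal(unname(s$rsd[2]), 20)  # mean 10, sample sd 2
  expect_identical(unname(s$rsd[3]), Inf)
  expect_identical(s$zero_mean_features, colnames(ds$intensities)[3])
  # zero-mean feature excluded from fraction denominators
  expect_equal(fraction_below(s, 30), 1)
  expect_equal(sum(s$counts), 2)
  expect_true(all(diff(s$cumulative) >= 0))
  expect_equal(s$cumulative[length(s$cumulative)], 1)

  expect_error(compute_rsd(make_dataset(m, roles = c("qc", "cell", "cell")), "qc"),
               "at least 2")
})

test_that("fraction_below uses strict inequality and is monotone", {
  rsds <- c(10, 20, 40, 60)
  expect_equal(fraction_below(rsds, 30), 0.5)
  expect_equal(fraction_below(rsds, 10), 0)   # strict: 10 not < 10
  expect_equal(fraction_below(rsds, 5), 0)
  thresholds <- c(5, 10, 15, 25, 45, 70)
  fracs <- vapply(thresholds, function(t) fraction_below(rsds, t), 0)
  expect_true(all(diff(fracs) >= 0))
  expect_error(fraction_below(rsds, 0), "positive")
})

test_that("RSD is invariant to positive rescaling of a feature", {
  sim <- small_sim()
  s1 <- compute_rsd(sim$dataset, "cell")
  ds2 <- sim$dataset
  ds2$intensities[, 5] <- ds2$intensities[, 5] * 3.7
  s2 <- compute_rsd(ds2, "cell")
  expect_equal(s1$rsd[5], s2$rsd[5], tolerance = 1e-12)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(8)
  m <- matrix(rpois(15, 20), 5, 3,
              dimnames = list(paste0("s", 1:5), paste0("mz_", 1:3)))
  ds <- make_dataset(m, roles = c("qc", "qc", "cell", "cell", "cell"))
  pca <- run_pca(ds, scale_features = FALSE)
  eig <- eigen(stats::cov(m), symmetric = TRUE)
  expect_equal(pca$explained_variance_pct,
               100 * eig$values / sum(eig$values), tolerance = 1e-8)
  centred <- scale(m, center = TRUE, scale = FALSE)
  scores_bf <- centred %*% eig$vectors
  for (k in 1:3)  # scores agree up to the fixed sign convention
    expect_equal(abs(unname(pca$scores[, k])), abs(unname(scores_bf[, k])),
                 tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (k in 1:3) {
    l <- pca$loadings[, k]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("PCA explained variances are sorted, sum to 100, and rank-1 data gives 100%", {
  sim <- small_sim()
  pca <- run_pca(sim$dataset)
  expect_true(all(diff(pca$explained_variance_pct) <= 1e-12))
  expect_equal(sum(pca$explained_variance_pct), 100, tolerance = 1e-8)

  # samples exactly on a line in feature space
  t <- seq(0, 1, length.out = 6)
  m <- outer(t, c(1, 2, 3)) + 5
  ds <- make_dataset(m, roles = c("qc", "qc", rep("cell", 4)))
  pca1 <- run_pca(ds, scale_features = FALSE)
  expect_equal(pca1$explained_variance_pct[1], 100, tolerance = 1e-8)

  ds_const <- make_dataset(matrix(3, 4, 3), roles = c("qc", rep("cell", 3)))
  expect_error(run_pca(ds_const), "constant")
})

test_that("correlation report: identity and monotone transforms preserve ranks", {
  sim <- small_sim()
  ds <- sim$dataset
  rep1 <- correlation_report(ds, ds)
  expect_true(all(rep1$per_sample_spearman == 1))
  expect_equal(rep1$log10_fit$slope, 1, tolerance = 1e-12)
  expect_equal(rep1$log10_fit$r_squared, 1, tolerance = 1e-12)
  expect_true(all(abs(diag(rep1$pearson) - 1) < 1e-12))
  expect_equal(rep1$pearson, t(rep1$pearson), tolerance = 1e-12)

  ds2 <- ds
  ds2$intensities <- ds2$intensities * 2
  rep2 <- correlation_report(ds, ds2)
  expect_true(all(rep2$per_sample_spearman == 1))

  # any strictly increasing row-wise transform preserves Spearman exactly
  ds3 <- ds
  ds3$intensities <- sqrt(ds3$intensities) + 1
  rep3 <- correlation_report(ds, ds3)
  expect_true(all(rep3$per_sample_spearman == 1))

  ds_bad <- make_dataset(matrix(1, 2, 2), roles = c("qc", "cell"))
  expect_error(correlation_report(ds, ds_bad), "share")
})

test_that("LOESS trends: constant and linear signals reproduce exactly", {
  n <- 20
  meta_roles <- c("qc", rep("cell", n - 1))
  m_const <- matrix(7, n, 2)
  ds_const <- make_dataset(m_const, roles = meta_roles)
  tr <- loess_trend(ds_const, colnames(ds_const$intensities)[1])
  expect_equal(tr$trend, rep(7, n), tolerance = 1e-6)

  m_lin <- cbind(3 + 2 * (1:n), 1)
  ds_lin <- make_dataset(m_lin, roles = meta_roles)
  tr_lin <- loess_trend(ds_lin, colnames(ds_lin$intensities)[1])
  expect_equal(tr_lin$trend, tr_lin$y, tolerance = 1e-6)

  # smaller span tracks a seeded noisy sinusoid more closely
  set.seed(33)
  y <- 10 + sin(seq(0, 4 * pi, length.out = 60)) + rnorm(60, 0, 0.2)
  ds_sin <- make_dataset(cbind(y, 1), roles = c("qc", rep("cell", 59)))
  f <- colnames(ds_sin$intensities)[1]
  r_small <- loess_trend(ds_sin, f, span = 0.3)
  r_large <- loess_trend(ds_sin, f, span = 0.9)
  expect_lt(mean((r_small$y - r_small$trend)^2),
            mean((r_large$y - r_large$trend)^2))

  expect_error(loess_trend(ds_sin, "mz_absent"), "not found")
})

test_that("silhouette mixing score separates the obvious cases", {
  set.seed(12)
  # two far-apart clouds
  m <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 20, 0.1), 20, 2))
  pca <- structure(list(scores = cbind(m, 0),
                        explained_variance_pct = c(60, 30, 10)),
                   class = "pca_result")
  labels <- rep(c("a", "b"), each = 20)
  expect_gt(batch_mixing_score(pca, labels), 0.9)

  # random labels on one cloud
  one <- matrix(rnorm(200), 100, 2)
  pca1 <- structure(list(scores = one, explained_variance_pct = c(50, 50)),
                    class = "pca_result")
  rand <- sample(rep(c("a", "b"), 50))
  expect_lt(abs(batch_mixing_score(pca1, rand)), 0.1)

  # identical duplicated points across groups cannot separate
  dup <- rbind(matrix(1:10, 5, 2), matrix(1:10, 5, 2))
  pca2 <- structure(list(scores = dup, explained_variance_pct = c(50, 50)),
                    class = "pca_result")
  expect_lte(batch_mixing_score(pca2, rep(c("a", "b"), each = 5)), 0)

  expect_error(batch_mixing_score(pca1, rep("a", 100)), "2 label groups")
})
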