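# The SVR stage: tuning, per-feature drift fits, correction application.

# Hand-built z-scored table around pooled stats; roles all QC unless given.
make_ztable <- function(z, meta, mu = NULL, sigma = NULL) {
  if (is.null(rownames(z))) rownames(z) <- meta$sample_id
  if (is.null(colnames(z))) colnames(z) <- sprintf("mz_%d", 100 + seq_len(ncol(z)))
  if (is.null(mu)) mu <- stats::setNames(rep(100, ncol(z)), colnames(z))
  if (is.null(sigma)) sigma <- stats::setNames(rep(10, ncol(z)), colnames(z))
  stats <- structure(list(mu = mu, sigma = sigma, n_qc = sum(meta$role == "qc"),
                          scope = "pooled"), class = "qc_stats")
  features <- data.frame(feature_id = colnames(z),
                         mz = seq_len(ncol(z)) + 100, polarity = NA,
                         total_counts = 1e4, snr = 10, stringsAsFactors = FALSE)
  structure(list(z = z, stats = stats, dropped_features = character(0),
                 meta = meta, features = features), class = "zscored_table")
}

qc_meta <- function(n, batch = "b1") {
  data.frame(sample_id = sprintf("%s_q%02d", batch, seq_len(n)), role = "qc",
             batch = batch, region = paste0(batch, "_r1"),
             acq_order = seq_len(n) - 1L, stringsAsFactors = FALSE)
}

test_that("a one-point grid is returned as-is with its CV score", {
  meta <- qc_meta(10)
  X <- encode_covariates(meta, "acq_order")
  y <- sin(X[, 1])
  cfg <- correction_config(c_grid = 7, epsilon_grid = 0.02, gamma_grid = list(0.5),
                           cv_folds = 5, seed = 3)
  hp <- tune_hyperparameters(y, X, cfg)
  expect_identical(hp$cost, 7)
  expect_identical(hp$epsilon, 0.02)
  expect_identical(hp$gamma, 0.5)
  expect_true(is.finite(hp$cv_mse))
})

test_that("ties in CV error break towards smallest C, then epsilon, then gamma", {
  meta <- qc_meta(10)
  X <- encode_covariates(meta, "acq_order")
  y <- rep(0, 10)  # every grid point scores exactly 0
  cfg <- correction_config(c_grid = c(100, 0.1, 10), epsilon_grid = c(0.1, 0.01),
                           gamma_grid = list(10, 0.1), cv_folds = 5, seed = 3)
  hp <- tune_hyperparameters(y, X, cfg)
  expect_identical(hp$cost, 0.1)
  expect_identical(hp$epsilon, 0.01)
  expect_identical(hp$gamma, 0.1)
})

test_that("on exactly linear drift the linear kernel matches the least-squares line", {
  meta <- qc_meta(20)
  X <- encode_covariates(meta, "acq_order")
  t <- X[, 1]
  y <- 2 * t - 1
  cfg_lin <- correction_config(kernel = "linear", c_grid = 1e4,
                               epsilon_grid = 0.001, gamma_grid = list(1),
                               cv_folds = 5, seed = 5)
  hp_lin <- tune_hyperparameters(y, X, cfg_lin)
  cfg_rbf <- correction_config(kernel = "rbf", c_grid = c(0.1, 1, 10, 100),
                               epsilon_grid = c(0.01, 0.1),
                               gamma_grid = list("scale", 1), cv_folds = 5,
                               seed = 5)
  hp_rbf <- tune_hyperparameters(y, X, cfg_rbf)
  expect_lte(hp_lin$cv_mse, hp_rbf$cv_mse)

  # fitted drift within 0.05 of the true line everywhere (OLS oracle)
  zt <- make_ztable(matrix(y, ncol = 1), meta)
  models <- fit_drift_models(zt, cfg_lin)
  pred <- predict(structure(list(models = models), class = "norm_svr_fit"),
                  newdata = meta)
  ols <- unname(stats::fitted(stats::lm(y ~ t)))
  expect_lt(max(abs(pred[, 1] - ols)), 0.05)
  expect_lt(max(abs(pred[, 1] - y)), 0.05)
})

test_that("flat QC signal yields near-zero drift; constant offsets are removed", {
  meta <- qc_meta(12)
  zt <- make_ztable(matrix(0, 12, 2), meta)
  cfg <- fast_config()
  models <- fit_drift_models(zt, cfg)
  res <- apply_correction(zt, models)
  expect_lt(max(abs(res$corrected_z$z)), max(cfg$epsilon_grid) + 1e-6)

  # constant +1 shift in z is absorbed by the model
  zt1 <- make_ztable(matrix(1, 12, 2), meta)
  res1 <- apply_correction(zt1, fit_drift_models(zt1, cfg))
  expect_lt(max(abs(res1$corrected_z$z)), max(cfg$epsilon_grid) + 1e-6)
})

test_that("cell samples never influence the fitted drift models", {
  sim <- small_sim()
  ds <- sim$dataset
  cfg <- fast_config(seed = 9)
  fit1 <- norm_svr(ds, cfg)
  ds2 <- ds
  cells <- which(ds$meta$role == "cell")
  perm <- rev(cells)
  ds2$intensities[cells, ] <- ds2$intensities[perm, ]  # scramble cell values
  fit2 <- norm_svr(ds2, cfg)
  expect_identical(fit1$drift, fit2$drift)
  expect_identical(coef(fit1), coef(fit2))
})

test_that("the full correction is deterministic given the seed", {
  sim <- small_sim()
  cfg <- fast_config(seed = 17)
  fit1 <- norm_svr(sim$dataset, cfg)
  fit2 <- norm_svr(sim$dataset, cfg)
  expect_identical(fit1$corrected$intensities, fit2$corrected$intensities)
  expect_identical(fit1$drift, fit2$drift)
})

test_that("with no drift and noise-free QC the correction is the identity", {
  sim <- simulate_tofsims(synthetic_config(
    n_cells_per_batch = 12, n_batches = 1, n_regions_per_batch = 1,
    n_features = 8, drift_amplitude = 0, tech_cv = 0, bio_cv = 0.3,
    seed = 6))
  cfg <- fast_config(sigma_policy = "epsilon")
  fit <- suppressMessages(norm_svr(sim$dataset, cfg))
  expect_equal(fit$corrected$intensities, sim$dataset$intensities,
               tolerance = 1e-8)
})

test_that("zero-variance features are dropped before modelling, not fitted", {
  sim <- small_sim()
  ds <- sim$dataset
  ds$intensities[ds$meta$role == "qc", 4] <- 123  # flat across all QC
  fit <- suppressMessages(norm_svr(ds, fast_config()))
  dropped_id <- colnames(sim$dataset$intensities)[4]
  expect_identical(fit$dropped_features, dropped_id)
  expect_false(dropped_id %in% colnames(fit$drift))
  expect_false(dropped_id %in% coef(fit)$feature_id)
})

test_that("unseen batch levels at prediction time are an error", {
  sim <- small_sim()
  fit <- norm_svr(sim$dataset, fast_config())
  new_meta <- sim$dataset$meta
  new_meta$batch[1] <- "batch99"
  expect_error(predict(fit, new_meta), "unseen during fitting")
})
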