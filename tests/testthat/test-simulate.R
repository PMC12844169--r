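# Synthetic-data generator: scheduling, generative bookkeeping, moments.

test_that("QC scheduling brackets the sequence at the configured ratio", {
  s8 <- schedule_qc(8, 4)
  expect_identical(s8, c("qc", rep("cell", 4), "qc", rep("cell", 4), "qc"))
  expect_identical(sum(s8 == "qc"), 3L)

  expect_identical(schedule_qc(1, 4), c("qc", "cell", "qc"))

  s60 <- schedule_qc(60, 4)
  expect_identical(sum(s60 == "qc"), 16L)  # 60/4 + 1
  expect_identical(sum(s60 == "cell"), 60L)
  expect_identical(s60[1], "qc")
  expect_identical(s60[length(s60)], "qc")

  # general rule: ceil(n/k) + 1 QC samples
  for (n in c(5, 7, 13)) for (k in c(2, 4, 5))
    expect_identical(sum(schedule_qc(n, k) == "qc"),
                     as.integer(ceiling(n / k) + 1))
})

test_that("generation is deterministic and validates its config", {
  cfg <- synthetic_config(n_cells_per_batch = 8, n_batches = 2,
                          n_features = 6, seed = 99)
  a <- simulate_tofsims(cfg)
  b <- simulate_tofsims(cfg)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$ground_truth$noise_mat, b$ground_truth$noise_mat)

  expect_error(synthetic_config(n_features = 0), "n_features")
  expect_error(synthetic_config(bio_cv = -1), "bio_cv")
  expect_error(synthetic_config(drift_feature_fraction = 1.5),
               "drift_feature_fraction")
})

test_that("the noise-free no-drift limit collapses to the base profile", {
  sim <- simulate_tofsims(synthetic_config(
    n_cells_per_batch = 8, n_batches = 1, n_regions_per_batch = 1,
    n_features = 5, bio_cv = 0, tech_cv = 0, batch_factor_sd = 0,
    region_factor_sd = 0, drift_amplitude = 0, seed = 4))
  m <- sim$dataset$intensities
  for (i in seq_len(nrow(m)))
    expect_equal(unname(m[i, ]), unname(sim$ground_truth$qc_reference_profile),
                 tolerance = 1e-12)
  # QC RSD exactly 0
  s <- compute_rsd(sim$dataset, "qc")
  expect_equal(unname(s$rsd), rep(0, 5))
})

test_that("stored components reconstruct the observed table exactly", {
  sim <- simulate_tofsims(synthetic_config(
    n_cells_per_batch = 10, n_batches = 2, n_features = 8, seed = 21))
  rec <- reconstruct_observed(sim$ground_truth)
  expect_equal(rec$intensities, sim$dataset$intensities, tolerance = 1e-12)

  # zeroing the drift component gives the drift-free counterfactual
  gt0 <- sim$ground_truth
  gt0$drift_mat[] <- 1
  rec0 <- reconstruct_observed(gt0)
  undrifted <- setdiff(colnames(rec0$intensities), gt0$drifted_features)
  expect_equal(rec0$intensities[, undrifted],
               sim$dataset$intensities[, undrifted], tolerance = 1e-12)
  drifted <- gt0$drifted_features
  expect_gt(max(abs(rec0$intensities[, drifted] -
                    sim$dataset$intensities[, drifted])), 0)

  # tampering with a component is detected as a mismatch
  gt_bad <- sim$ground_truth
  gt_bad$batch_factors_mat[1, 1] <- gt_bad$batch_factors_mat[1, 1] * 2
  rec_bad <- reconstruct_observed(gt_bad)
  expect_false(isTRUE(all.equal(rec_bad$intensities,
                                sim$dataset$intensities, tolerance = 1e-12)))

  gt_miss <- sim$ground_truth
  gt_miss$noise_mat <- NULL
  expect_error(reconstruct_observed(gt_miss), "noise_mat")
})

test_that("QC rows carry no biological variation; cells match bio_cv", {
  sim <- simulate_tofsims(synthetic_config(
    n_cells_per_batch = 500, n_batches = 1, n_regions_per_batch = 1,
    n_features = 10, bio_cv = 0.3, tech_cv = 0, batch_factor_sd = 0,
    region_factor_sd = 0, drift_amplitude = 0, seed = 77))
  gt <- sim$ground_truth
  qc <- sim$dataset$meta$role == "qc"
  # QC profiles are exactly the reference profile
  for (j in 1:10)
    expect_equal(unname(gt$profiles[qc, j]),
                 rep(unname(gt$qc_reference_profile[j]), sum(qc)))
  # empirical between-cell CV within 15% relative of bio_cv
  cells <- sim$dataset$intensities[!qc, ]
  cv <- apply(cells, 2, sd) / colMeans(cells)
  expect_true(all(abs(cv - 0.3) / 0.3 < 0.15))
})

test_that("raw QC RSD of drifted features grows with drift amplitude", {
  # isolate the drift component: no offsets, no technical noise, so each
  # feature's QC RSD is a * sd(s) / (1 + a * mean(s)), increasing in a
  base <- function(a) synthetic_config(
    n_cells_per_batch = 20, n_batches = 1, n_regions_per_batch = 1,
    n_features = 12, drift_amplitude = a, drift_feature_fraction = 1,
    tech_cv = 0, batch_factor_sd = 0, region_factor_sd = 0, seed = 13)
  rsd_at <- function(a) {
    sim <- simulate_tofsims(base(a))
    compute_rsd(sim$dataset, "qc")$rsd
  }
  r <- vapply(c(0, 0.2, 0.4, 0.6), rsd_at, numeric(12))
  for (j in 1:12) expect_true(all(diff(r[j, ]) > 0))
})
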