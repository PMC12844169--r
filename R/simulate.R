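#' Configuration for the synthetic ToF-SIMS single-cell generator
#'
#' Defines the study conditions the generator reproduces: a multi-batch,
#' multi-region single-cell acquisition with QC samples interleaved at a
#' fixed cell:QC ratio, log-normally heterogeneous cell profiles around a
#' shared base profile, a fixed QC reference profile, multiplicative batch
#' and region offsets, smooth within-sequence signal drift on a fraction of
#' features, and multiplicative counting noise.
#'
#' Defaults emulate the three-batch design: 3 batches of 52 cells each with
#' QC every 4 cells (14 QC per batch, 156 cells + 42 QC in total), 457
#' feature ions with base mean intensities spread over four decades
#' (log10 range 1.5-5.5), biological CV 30%, technical CV 10%, per-feature
#' batch offsets with log-sd 0.5 and region offsets with log-sd 0.3 (strong
#' enough that between-batch variation dominates the leading principal
#' components of the raw table, as observed experimentally), and relative
#' drift of amplitude 0.4 affecting 80% of features.
#'
#' @param n_cells_per_batch cells per batch (default 52).
#' @param n_batches number of batches (default 3).
#' @param n_regions_per_batch collection regions per batch (default 3); the
#'   acquisition sequence is split into contiguous region segments, as when
#'   regions of a wafer are acquired one after another.
#' @param n_features number of feature ions (default 457).
#' @param qc_ratio k, meaning one QC after every k cells (default 4).
#' @param base_profile length-2 range of per-feature log10 mean intensity
#'   (default c(1.5, 5.5)).
#' @param bio_cv between-cell biological coefficient of variation (default 0.3).
#' @param tech_cv technical (counting/instrument) coefficient of variation
#'   applied to every observation (default 0.1).
#' @param batch_factor_sd log-scale sd of multiplicative batch offsets
#'   (default 0.5).
#' @param region_factor_sd log-scale sd of multiplicative region offsets
#'   (default 0.3).
#' @param drift_amplitude maximum |relative drift| over a sequence (default
#'   0.4, i.e. up to +/-40% of signal).
#' @param drift_shape \code{"sinusoidal"} (default), \code{"linear"} or
#'   \code{"exponential-decay"}; the shape is scaled to [-1, 1] over the
#'   sequence.
#' @param drift_feature_fraction fraction of features affected by drift
#'   (default 0.8).
#' @param per_feature_factors draw batch/region offsets independently per
#'   feature (default TRUE; the setting under which plain row-sum
#'   normalization cannot remove them). FALSE shares one factor across all
#'   features.
#' @param per_feature_drift give each affected feature its own drift curve
#'   (random phase/sign; default TRUE). FALSE applies one common curve —
#'   the feature-homogeneous drift limit.
#' @param seed integer seed for all randomness (default 1).
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_cells_per_batch = 52L, n_batches = 3L,
                             n_regions_per_batch = 3L, n_features = 457L,
                             qc_ratio = 4L, base_profile = c(1.5, 5.5),
                             bio_cv = 0.3, tech_cv = 0.1,
                             batch_factor_sd = 0.5, region_factor_sd = 0.3,
                             drift_amplitude = 0.4,
                             drift_shape = c("sinusoidal", "linear",
                                             "exponential-decay"),
                             drift_feature_fraction = 0.8,
                             per_feature_factors = TRUE,
                             per_feature_drift = TRUE,
                             seed = 1L) {
  drift_shape <- match.arg(drift_shape)
  cfg <- list(n_cells_per_batch = as.integer(n_cells_per_batch),
              n_batches = as.integer(n_batches),
              n_regions_per_batch = as.integer(n_regions_per_batch),
              n_features = as.integer(n_features),
              qc_ratio = as.integer(qc_ratio),
              base_profile = as.numeric(base_profile),
              bio_cv = bio_cv, tech_cv = tech_cv,
              batch_factor_sd = batch_factor_sd,
              region_factor_sd = region_factor_sd,
              drift_amplitude = drift_amplitude,
              drift_shape = drift_shape,
              drift_feature_fraction = drift_feature_fraction,
              per_feature_factors = isTRUE(per_feature_factors),
              per_feature_drift = isTRUE(per_feature_drift),
              seed = as.integer(seed))
  for (f in c("n_cells_per_batch", "n_batches", "n_regions_per_batch",
              "n_features", "qc_ratio"))
    if (cfg[[f]] < 1L) stop("invalid config: ", f, " must be >= 1")
  for (f in c("bio_cv", "tech_cv", "batch_factor_sd", "region_factor_sd",
              "drift_amplitude"))
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  if (cfg$drift_feature_fraction < 0 || cfg$drift_feature_fraction > 1)
    stop("invalid config: drift_feature_fraction must be in [0, 1]")
  if (length(cfg$base_profile) != 2L || diff(cfg$base_profile) < 0)
    stop("invalid config: base_profile must be an increasing length-2 range")
  if (cfg$drift_amplitude >= 1)
    stop("invalid config: drift_amplitude must be < 1 (relative drift)")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d batch(es) x %d cells (+QC 1:%d), %d regions/batch, %d features\n",
    x$n_batches, x$n_cells_per_batch, x$qc_ratio, x$n_regions_per_batch,
    x$n_features))
  cat(sprintf("  bio_cv %.2f, tech_cv %.2f, batch sd %.2f, region sd %.2f\n",
              x$bio_cv, x$tech_cv, x$batch_factor_sd, x$region_factor_sd))
  cat(sprintf("  drift: %s, amplitude %.2f, %.0f%% of features; seed %d\n",
              x$drift_shape, x$drift_amplitude,
              100 * x$drift_feature_fraction, x$seed))
  invisible(x)
}

#' QC interleaving schedule
#'
#' Builds the within-batch acquisition role sequence: a QC sample first, one
#' QC after every \code{qc_ratio} cells, and a closing QC after the last
#' cells, so the sequence is bracketed by QC measurements. The number of QC
#' samples is \code{ceiling(n_cells / qc_ratio) + 1}.
#'
#' @param n_cells number of cell samples (>= 1).
#' @param qc_ratio cells per QC (>= 1, default 4).
#' @return character vector of roles (\code{"qc"} / \code{"cell"}) in
#'   acquisition order; positions are the 0-based \code{acq_order}.
#' @examples
#' schedule_qc(8, 4)   # qc c c c c qc c c c c qc
#' @export
schedule_qc <- function(n_cells, qc_ratio = 4L) {
  n_cells <- as.integer(n_cells); qc_ratio <- as.integer(qc_ratio)
  if (n_cells < 1L || qc_ratio < 1L)
    stop("n_cells and qc_ratio must be >= 1")
  roles <- "qc"
  left <- n_cells
  while (left > 0L) {
    k <- min(qc_ratio, left)
    roles <- c(roles, rep("cell", k), "qc")
    left <- left - k
  }
  roles
}

# Drift shape scaled to [-1, 1] at relative positions t in [0, 1].
drift_shape_fn <- function(shape, t, phase = 0) {
  switch(shape,
         "linear" = 2 * t - 1,
         "exponential-decay" = {
           e <- exp(-3 * t)
           2 * (e - exp(-3)) / (1 - exp(-3)) - 1
         },
         "sinusoidal" = sin(2 * pi * (t + phase)),
         stop("unknown drift shape: ", shape))
}

#' Generate a synthetic single-cell ToF-SIMS dataset with ground truth
#'
#' Draws a dataset under the generative model
#' \deqn{x_{ij} = p_{ij} \cdot b_{B(i),j} \cdot r_{R(i),j} \cdot
#'   (1 + A\, s_j(t_i)) \cdot \eta_{ij}}
#' where \eqn{p_{ij}} is the drift-free profile (the shared QC reference
#' profile for QC rows; a log-normal per-cell profile with CV
#' \code{bio_cv} for cells), \eqn{b} and \eqn{r} are log-normal batch and
#' region offsets, \eqn{s_j} is the drift shape of amplitude
#' \code{drift_amplitude} evaluated at the relative acquisition position
#' \eqn{t_i}, and \eqn{\eta_{ij}} is log-normal technical noise with CV
#' \code{tech_cv}. All randomness comes from \code{config$seed}; negative
#' intensities are impossible by construction.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{dataset} (an \code{sc_dataset}) and
#'   \code{ground_truth} (class \code{sc_ground_truth}): the component
#'   matrices \code{profiles}, \code{batch_factors_mat},
#'   \code{region_factors_mat}, \code{drift_mat}, \code{noise_mat} whose
#'   elementwise product is the observed table; plus
#'   \code{qc_reference_profile}, \code{batch_factors} /
#'   \code{region_factors} (structured), \code{drift_z} (the systematic
#'   technical deviation per sample and feature, in QC z-score units,
#'   see Details), \code{drifted_features}, and \code{config}.
#'
#' @details \code{drift_z} is the ground-truth technical-error surface on
#' the z-score scale the correction operates on: for sample i and feature j
#' it is \eqn{(q_j b_{B(i),j} r_{R(i),j} (1 + A s_j(t_i)) - \mu_j) /
#' \sigma_j}, the noise-free deviation of a QC measurement at sample i's
#' acquisition covariates from the pooled QC mean, in pooled QC standard
#' deviations (features with zero QC variance get NA). Estimated drift from
#' the correction can be compared against it directly.
#' @export
simulate_tofsims <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_tofsims_impl(config))
}

simulate_tofsims_impl <- function(cfg) {
  p <- cfg$n_features
  mz <- sort(round(stats::runif(p, 50, 400), 4))
  feature_ids <- sprintf("mz_%.4f", mz)
  # base (= QC reference) profile, log-uniform across the stated decade range
  qc_ref <- 10^stats::runif(p, cfg$base_profile[1], cfg$base_profile[2])
  names(qc_ref) <- feature_ids

  # per-batch schedules and metadata
  meta_list <- list()
  for (b in seq_len(cfg$n_batches)) {
    roles <- schedule_qc(cfg$n_cells_per_batch, cfg$qc_ratio)
    n <- length(roles)
    region_idx <- ceiling(seq_len(n) / n * cfg$n_regions_per_batch)
    meta_list[[b]] <- data.frame(
      sample_id = sprintf("b%d_%s%03d", b, ifelse(roles == "qc", "qc", "c"),
                          seq_len(n)),
      role = roles,
      batch = paste0("batch", b),
      region = sprintf("b%d_r%d", b, region_idx),
      acq_order = seq_len(n) - 1L,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_list)
  n <- nrow(meta)

  sdlog <- function(cv) sqrt(log(1 + cv^2))

  # drift-free profiles: QC rows share the reference; cells are log-normal
  profiles <- matrix(qc_ref, n, p, byrow = TRUE,
                     dimnames = list(meta$sample_id, feature_ids))
  is_cell <- meta$role == "cell"
  if (cfg$bio_cv > 0 && any(is_cell)) {
    bio <- matrix(exp(stats::rnorm(sum(is_cell) * p, 0, sdlog(cfg$bio_cv))),
                  sum(is_cell), p)
    profiles[is_cell, ] <- profiles[is_cell, , drop = FALSE] * bio
  }

  # multiplicative batch / region offsets
  batches <- unique(meta$batch)
  regions <- unique(meta$region)
  nfac <- function(sd, groups) {
    k <- length(groups)
    m <- if (cfg$per_feature_factors)
      matrix(exp(stats::rnorm(k * p, 0, sd)), k, p)
    else matrix(exp(stats::rnorm(k, 0, sd)), k, p)
    dimnames(m) <- list(groups, feature_ids)
    m
  }
  batch_factors <- nfac(cfg$batch_factor_sd, batches)
  region_factors <- nfac(cfg$region_factor_sd, regions)
  B <- batch_factors[meta$batch, , drop = FALSE]
  Rg <- region_factors[meta$region, , drop = FALSE]
  dimnames(B) <- dimnames(Rg) <- dimnames(profiles)

  # smooth within-sequence drift on a subset of features
  n_drift <- round(cfg$drift_feature_fraction * p)
  drifted <- sort(sample.int(p, n_drift))
  phases <- if (cfg$per_feature_drift) stats::runif(p) else rep(0, p)
  signs <- if (cfg$per_feature_drift) sample(c(-1, 1), p, replace = TRUE)
           else rep(1, p)
  omax <- stats::ave(meta$acq_order, meta$batch, FUN = max)
  t_rel <- meta$acq_order / pmax(omax, 1L)
  D <- matrix(1, n, p, dimnames = dimnames(profiles))
  for (j in drifted)
    D[, j] <- 1 + cfg$drift_amplitude * signs[j] *
      drift_shape_fn(cfg$drift_shape, t_rel, phases[j])

  # technical noise on every observation
  N <- matrix(1, n, p, dimnames = dimnames(profiles))
  if (cfg$tech_cv > 0)
    N[] <- exp(stats::rnorm(n * p, 0, sdlog(cfg$tech_cv)))

  observed <- profiles * B * Rg * D * N
  features <- data.frame(feature_id = feature_ids, mz = mz,
                         polarity = "negative",
                         total_counts = unname(colSums(observed)),
                         snr = round(stats::runif(p, 3, 30), 2),
                         stringsAsFactors = FALSE)
  table <- new_feature_table(observed, features)
  ds <- join_dataset(table, meta)

  # ground-truth systematic deviation in pooled-QC z units
  qc_rows <- meta$role == "qc"
  tech_surface <- matrix(qc_ref, n, p, byrow = TRUE) * B * Rg * D
  x_qc <- observed[qc_rows, , drop = FALSE]
  mu <- colMeans(x_qc)
  sig <- apply(x_qc, 2L, stats::sd)
  drift_z <- sweep(sweep(tech_surface, 2L, mu), 2L,
                   ifelse(sig > 0, sig, NA_real_), `/`)
  dimnames(drift_z) <- dimnames(profiles)

  gt <- structure(list(profiles = profiles, batch_factors_mat = B,
                       region_factors_mat = Rg, drift_mat = D, noise_mat = N,
                       qc_reference_profile = qc_ref,
                       batch_factors = batch_factors,
                       region_factors = region_factors,
                       drift_z = drift_z,
                       drifted_features = feature_ids[drifted],
                       config = cfg),
                  class = "sc_ground_truth")
  list(dataset = ds, ground_truth = gt)
}

#' @export
print.sc_ground_truth <- function(x, ...) {
  cat(sprintf("sc_ground_truth: %d samples x %d features; %d drifted feature(s)\n",
              nrow(x$profiles), ncol(x$profiles), length(x$drifted_features)))
  invisible(x)
}

#' Rebuild the observed table from stored ground-truth components
#'
#' Validates the generator's bookkeeping: the elementwise product of the
#' stored profile, batch-offset, region-offset, drift and noise matrices is
#' exactly the observed table. Zeroing a component (e.g. \code{drift_mat})
#' yields the corresponding counterfactual table.
#'
#' @param gt an \code{sc_ground_truth}.
#' @return a \code{feature_table} of the recombined intensities.
#' @export
reconstruct_observed <- function(gt) {
  stopifnot(inherits(gt, "sc_ground_truth"))
  need <- c("profiles", "batch_factors_mat", "region_factors_mat",
            "drift_mat", "noise_mat")
  miss <- need[!vapply(need, function(f) !is.null(gt[[f]]), TRUE)]
  if (length(miss))
    stop("ground truth missing component(s): ", paste(miss, collapse = ", "))
  m <- gt$profiles * gt$batch_factors_mat * gt$region_factors_mat *
    gt$drift_mat * gt$noise_mat
  new_feature_table(m, NULL) |> suppressWarnings()
}
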