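#' Correction configuration
#'
#' Collects the tunable settings of the QC-driven drift correction. The
#' hyperparameter grid is searched exhaustively with seeded k-fold
#' cross-validation on the QC samples of each fitting unit; the grid point
#' minimizing the mean cross-validated squared error wins, with ties broken
#' towards the smallest cost, then the smallest epsilon, then the smallest
#' gamma (a deterministic, least-flexible-model preference).
#'
#' Default grids mirror common QC-based SVR practice: cost
#' \eqn{C \in \{0.1, 1, 10, 100\}}, tube width
#' \eqn{\epsilon \in \{0.01, 0.05, 0.1\}} (z-score units), kernel width
#' \eqn{\gamma \in \{\mathrm{scale}, 0.1, 1, 10\}} where \code{"scale"}
#' resolves to \eqn{1 / (p \cdot \mathrm{var}(X))} for a p-column design
#' matrix. For the linear kernel \eqn{\gamma} is inert and the grid collapses
#' to a single value.
#'
#' @param kernel \code{"rbf"} (default) or \code{"linear"}.
#' @param c_grid positive costs to search.
#' @param epsilon_grid non-negative epsilon-tube widths to search.
#' @param gamma_grid positive kernel widths and/or the string \code{"scale"}.
#' @param cv_folds number of cross-validation folds (>= 2, default 5).
#' @param covariates subset of \code{c("acq_order", "region", "batch")} used
#'   as drift predictors.
#' @param scope \code{"auto"} (per-batch models when more than one batch is
#'   present, pooled otherwise), \code{"pooled"}, or \code{"per_batch"}.
#' @param fold_type \code{"shuffled"} (seeded random fold assignment, default)
#'   or \code{"blocked"} (acquisition-order-contiguous folds, a harder,
#'   extrapolation-honest split).
#' @param stats_scope scope of the QC statistics for the Z-score stage
#'   (\code{"pooled"}, matching the use of all QC samples, or
#'   \code{"per_batch"}).
#' @param sigma_policy handling of zero-QC-variance features in the Z-score
#'   stage: \code{"drop"} (default) or \code{"epsilon"}.
#' @param seed integer seed controlling fold shuffling (and nothing else).
#' @return object of class \code{correction_config}.
#' @export
correction_config <- function(kernel = c("rbf", "linear"),
                              c_grid = c(0.1, 1, 10, 100),
                              epsilon_grid = c(0.01, 0.05, 0.1),
                              gamma_grid = list("scale", 0.1, 1, 10),
                              cv_folds = 5L,
                              covariates = c("acq_order", "region", "batch"),
                              scope = c("auto", "pooled", "per_batch"),
                              fold_type = c("shuffled", "blocked"),
                              stats_scope = c("pooled", "per_batch"),
                              sigma_policy = c("drop", "epsilon"),
                              seed = 1L) {
  kernel <- match.arg(kernel)
  scope <- match.arg(scope)
  fold_type <- match.arg(fold_type)
  stats_scope <- match.arg(stats_scope)
  sigma_policy <- match.arg(sigma_policy)
  if (!is.list(gamma_grid)) gamma_grid <- as.list(gamma_grid)
  if (length(c_grid) == 0L || length(epsilon_grid) == 0L || length(gamma_grid) == 0L)
    stop("hyperparameter grids must be non-empty")
  if (any(c_grid <= 0)) stop("c_grid values must be positive")
  if (any(epsilon_grid < 0)) stop("epsilon_grid values must be non-negative")
  for (g in gamma_grid)
    if (!identical(g, "scale") && (!is.numeric(g) || g <= 0))
      stop("gamma_grid entries must be positive numbers or \"scale\"")
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(kernel = kernel, c_grid = sort(c_grid),
                 epsilon_grid = sort(epsilon_grid), gamma_grid = gamma_grid,
                 cv_folds = cv_folds, covariates = covariates, scope = scope,
                 fold_type = fold_type, stats_scope = stats_scope,
                 sigma_policy = sigma_policy, seed = as.integer(seed)),
            class = "correction_config")
}

#' @export
print.correction_config <- function(x, ...) {
  cat(sprintf("correction_config: kernel %s, %d-fold CV (%s folds), scope %s\n",
              x$kernel, x$cv_folds, x$fold_type, x$scope))
  cat(sprintf("  grid: %d C x %d epsilon x %d gamma; covariates: %s; seed %d\n",
              length(x$c_grid), length(x$epsilon_grid), length(x$gamma_grid),
              paste(x$covariates, collapse = "+"), x$seed))
  invisible(x)
}

# Resolve "scale" to sklearn-style 1 / (p * var(X)); guard degenerate X.
resolve_gamma <- function(g, X) {
  if (identical(g, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(g)
}

# eps-regression fit with a degenerate-case fallback: when every training
# point lies inside the epsilon tube there are no support vectors (libsvm
# cannot predict from an empty model); the SVR solution is then a constant,
# taken as mean(y).
svr_fit <- function(X, y, kernel, cost, epsilon, gamma) {
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
  if (fit$tot.nSV == 0L)
    structure(list(constant = mean(y)), class = "svr_constant")
  else fit
}

svr_predict <- function(fit, X) {
  if (inherits(fit, "svr_constant")) rep(fit$constant, nrow(X))
  else unname(stats::predict(fit, X))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Seeded fold assignment for n points; shuffled or contiguous in `order_by`.
make_folds <- function(n, k, seed, fold_type = "shuffled", order_by = NULL) {
  if (n < k)
    stop("fewer QC samples (", n, ") than cv_folds (", k,
         "); lower cv_folds in the configuration")
  base <- rep(seq_len(k), length.out = n)
  folds <- integer(n)
  if (fold_type == "shuffled") {
    perm <- with_seed(seed, sample.int(n))
    folds[perm] <- base
  } else {
    folds[order(order_by)] <- sort(base)
  }
  folds
}

#' Tune SVR hyperparameters for one feature by grid search + k-fold CV
#'
#' Exhaustively evaluates every (C, epsilon, gamma) grid point by k-fold
#' cross-validation on the QC observations of one feature and returns the
#' point with minimum mean held-out squared error. Ties are broken towards
#' the smallest C, then epsilon, then gamma.
#'
#' @param y numeric vector of QC z-scores for one feature.
#' @param X design matrix for the same QC rows
#'   (\code{\link{encode_covariates}}).
#' @param config a \code{\link{correction_config}}.
#' @param folds optional precomputed fold assignment (integers in
#'   \code{1:cv_folds}); computed from the config seed when missing.
#' @return list with \code{cost}, \code{epsilon}, \code{gamma} (numeric),
#'   \code{gamma_label} (\code{"scale"} or the number), and \code{cv_mse}.
#' @export
tune_hyperparameters <- function(y, X, config, folds = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(folds))
    folds <- make_folds(n, config$cv_folds, config$seed, config$fold_type,
                        order_by = seq_len(n))
  gamma_grid <- config$gamma_grid
  if (config$kernel == "linear") gamma_grid <- gamma_grid[1L]
  gvals <- vapply(gamma_grid, function(g) resolve_gamma(g, X), 0)
  glabs <- vapply(gamma_grid, function(g) if (identical(g, "scale")) "scale"
                  else format(g), "")
  ord <- order(gvals)
  gvals <- gvals[ord]; glabs <- glabs[ord]
  kern <- if (config$kernel == "rbf") "radial" else "linear"
  best <- NULL
  for (ci in config$c_grid) for (ei in config$epsilon_grid)
    for (gi in seq_along(gvals)) {
      sse <- 0
      for (f in sort(unique(folds))) {
        test <- folds == f
        fit <- svr_fit(X[!test, , drop = FALSE], y[!test], kern,
                       ci, ei, gvals[gi])
        pred <- svr_predict(fit, X[test, , drop = FALSE])
        sse <- sse + sum((y[test] - pred)^2)
      }
      mse <- sse / n
      if (!is.finite(mse)) stop("non-finite CV score at C=", ci, ", epsilon=", ei)
      if (is.null(best) || mse < best$cv_mse)
        best <- list(cost = ci, epsilon = ei, gamma = gvals[gi],
                     gamma_label = glabs[gi], cv_mse = mse)
    }
  best
}

#' Fit per-feature drift models on QC samples
#'
#' For every retained feature ion independently, fits an epsilon-insensitive
#' kernel regression of the feature's QC z-scores on the encoded acquisition
#' covariates. Only QC rows ever enter the fit (the QC-driven contract: cell
#' intensities cannot influence the drift estimate). With more than one batch
#' and \code{scope = "auto"} or \code{"per_batch"}, an independent model set
#' is fitted per batch, since drift curves are batch-specific; the batch
#' indicator is then dropped from the within-batch design.
#'
#' @param z a \code{zscored_table}.
#' @param config a \code{\link{correction_config}}.
#' @return object of class \code{drift_model_set}: per fitting unit, the
#'   fitted \code{e1071::svm} model and chosen hyperparameters per feature,
#'   the covariate encoding, and the rows the unit covers.
#' @export
fit_drift_models <- function(z, config = correction_config()) {
  stopifnot(inherits(z, "zscored_table"))
  meta <- z$meta
  batches <- unique(meta$batch)
  scope <- config$scope
  if (scope == "auto") scope <- if (length(batches) > 1L) "per_batch" else "pooled"
  units <- if (scope == "per_batch") {
    out <- lapply(batches, function(b) which(meta$batch == b))
    names(out) <- batches
    out
  } else list(pooled = seq_len(nrow(meta)))
  fitted_units <- lapply(names(units), function(uname) {
    rows <- units[[uname]]
    m <- meta[rows, , drop = FALSE]
    covs <- config$covariates
    if (scope == "per_batch") covs <- setdiff(covs, "batch")
    if (length(unique(m$region)) < 2L) covs <- setdiff(covs, "region")
    if (length(covs) == 0L) covs <- "acq_order"
    X_all <- encode_covariates(m, covs)
    qc_local <- which(m$role == "qc")
    if (length(qc_local) < config$cv_folds)
      stop("unit '", uname, "' has ", length(qc_local),
           " QC samples but cv_folds = ", config$cv_folds,
           "; lower cv_folds in the configuration")
    X_qc <- X_all[qc_local, , drop = FALSE]
    folds <- make_folds(length(qc_local), config$cv_folds, config$seed,
                        config$fold_type,
                        order_by = m$acq_order[qc_local])
    kern <- if (config$kernel == "rbf") "radial" else "linear"
    feats <- colnames(z$z)
    models <- vector("list", length(feats))
    hyper <- vector("list", length(feats))
    for (j in seq_along(feats)) {
      y <- z$z[rows, j][qc_local]
      hp <- tune_hyperparameters(y, X_qc, config, folds = folds)
      fit <- svr_fit(X_qc, y, kern, hp$cost, hp$epsilon, hp$gamma)
      models[[j]] <- fit
      hyper[[j]] <- data.frame(feature_id = feats[j], unit = uname,
                               cost = hp$cost, epsilon = hp$epsilon,
                               gamma = hp$gamma, gamma_label = hp$gamma_label,
                               cv_mse = hp$cv_mse, stringsAsFactors = FALSE)
    }
    names(models) <- feats
    list(rows = rows, models = models,
         hyper = do.call(rbind, hyper),
         levels = attr(X_all, "levels"), covariates = covs)
  })
  names(fitted_units) <- names(units)
  structure(list(units = fitted_units, scope = scope, config = config,
                 feature_ids = colnames(z$z)),
            class = "drift_model_set")
}

#' @export
print.drift_model_set <- function(x, ...) {
  cat(sprintf("drift_model_set: %d feature(s) x %d unit(s) (%s scope, %s kernel)\n",
              length(x$feature_ids), length(x$units), x$scope, x$config$kernel))
  invisible(x)
}

# Drift predictions for every row of `meta`, all features: n x p matrix.
predict_drift <- function(models, meta) {
  stopifnot(inherits(models, "drift_model_set"))
  meta <- as.data.frame(meta)
  p <- length(models$feature_ids)
  D <- matrix(NA_real_, nrow(meta), p,
              dimnames = list(meta$sample_id, models$feature_ids))
  if (models$scope == "per_batch") {
    miss <- setdiff(unique(meta$batch), names(models$units))
    if (length(miss))
      stop("batch level(s) unseen during fitting: ", paste(miss, collapse = ", "))
  }
  for (uname in names(models$units)) {
    u <- models$units[[uname]]
    rows <- if (models$scope == "per_batch") which(meta$batch == uname)
            else seq_len(nrow(meta))
    if (!length(rows)) next
    X <- encode_covariates(meta[rows, , drop = FALSE], u$covariates,
                           levels = u$levels)
    for (j in seq_len(p))
      D[rows, j] <- svr_predict(u$models[[j]], X)
  }
  D
}

#' Subtract predicted drift from a z-scored table
#'
#' Applies the fitted drift models to every sample (cells and QC alike):
#' \eqn{z^{corr}_{ij} = z_{ij} - \hat d_j(\mathrm{covariates}_i)}, then
#' back-transforms to the raw intensity scale. A region or batch level absent
#' from the training metadata is an error; categorical drift estimates are
#' never extrapolated.
#'
#' @param z a \code{zscored_table}.
#' @param models a \code{drift_model_set} covering the features of \code{z}.
#' @param meta metadata aligned to \code{z} rows (defaults to the metadata
#'   carried in \code{z}).
#' @return object of class \code{correction_result}: list with
#'   \code{corrected} (raw-scale \code{feature_table}), \code{corrected_z}
#'   (\code{zscored_table}), \code{drift} (predicted drift matrix, z units),
#'   \code{models}, and \code{diagnostics} (per-feature QC RSD before/after,
#'   percent).
#' @export
apply_correction <- function(z, models, meta = z$meta) {
  stopifnot(inherits(z, "zscored_table"), inherits(models, "drift_model_set"))
  if (!identical(colnames(z$z), models$feature_ids))
    stop("feature sets of z-table and drift models differ")
  D <- predict_drift(models, meta)
  zc <- z
  zc$z <- z$z - D
  raw_before <- inverse_zscore(z, meta)
  corrected <- inverse_zscore(zc, meta)
  qc <- meta$role == "qc"
  rsd <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2L, stats::sd)
    ifelse(mu == 0, Inf, 100 * s / mu)
  }
  diagnostics <- data.frame(
    feature_id = colnames(z$z),
    qc_rsd_before = rsd(raw_before$intensities[qc, , drop = FALSE]),
    qc_rsd_after = rsd(corrected$intensities[qc, , drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(corrected = corrected, corrected_z = zc, drift = D,
                 models = models, diagnostics = diagnostics),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("correction_result: %d samples x %d features\n",
              nrow(x$corrected$intensities), ncol(x$corrected$intensities)))
  cat(sprintf("  median QC RSD: %.1f%% -> %.1f%%\n",
              stats::median(x$diagnostics$qc_rsd_before),
              stats::median(x$diagnostics$qc_rsd_after)))
  invisible(x)
}

#' Fit the two-stage QC-driven drift correction
#'
#' The main fitting function. Runs the full two-stage procedure on a
#' dataset: (1) the Norm stage, per-feature Z-score normalization against QC
#' statistics (\code{\link{compute_qc_stats}},
#' \code{\link{zscore_transform}}); (2) the SVR stage, per-feature
#' epsilon-insensitive kernel regression of QC z-scores on acquisition
#' covariates, tuned by seeded grid search with k-fold cross-validation,
#' whose predicted technical-error surface is subtracted from every sample
#' before back-transforming to the raw intensity scale
#' (\code{\link{fit_drift_models}}, \code{\link{apply_correction}}).
#'
#' The procedure is deterministic given \code{config$seed}: two runs with the
#' same seed yield bit-identical corrected tables.
#'
#' @param ds an \code{sc_dataset} (see \code{\link{join_dataset}}).
#' @param config a \code{\link{correction_config}}.
#' @return object of class \code{norm_svr_fit}, with methods
#'   \code{print}, \code{summary}, \code{coef} (per-feature hyperparameter
#'   audit), \code{fitted} (drift surface, z units), \code{residuals}
#'   (corrected z-scores), \code{predict} (drift at new metadata) and
#'   \code{plot}. Components: \code{corrected} (raw-scale
#'   \code{sc_dataset}), \code{corrected_z}, \code{drift}, \code{models},
#'   \code{qc_stats}, \code{diagnostics}, \code{dropped_features},
#'   \code{config}, \code{call}.
#' @examples
#' sim <- simulate_tofsims(synthetic_config(
#'   n_cells_per_batch = 16, n_batches = 1, n_features = 12, seed = 7))
#' fit <- norm_svr(sim$dataset, correction_config(
#'   c_grid = c(1, 10), epsilon_grid = 0.05, gamma_grid = list("scale"),
#'   cv_folds = 3))
#' fit
#' head(coef(fit))
#' @export
norm_svr <- function(ds, config = correction_config()) {
  stopifnot(inherits(ds, "sc_dataset"))
  cl <- match.call()
  stats <- compute_qc_stats(ds, scope = config$stats_scope)
  z <- zscore_transform(ds, stats, sigma_policy = config$sigma_policy)
  models <- fit_drift_models(z, config)
  res <- apply_correction(z, models)
  corrected_ds <- structure(list(intensities = res$corrected$intensities,
                                 features = res$corrected$features,
                                 meta = ds$meta),
                            class = "sc_dataset")
  structure(list(corrected = corrected_ds, corrected_z = res$corrected_z,
                 drift = res$drift, models = models, qc_stats = stats,
                 diagnostics = res$diagnostics,
                 dropped_features = z$dropped_features,
                 n_clipped = attr(res$corrected, "n_clipped"),
                 config = config, call = cl),
            class = "norm_svr_fit")
}
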