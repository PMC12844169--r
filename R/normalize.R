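#' Per-feature QC statistics
#'
#' Computes, for every feature ion, the mean and standard deviation of its
#' intensity across QC samples. These are the parameters of the Z-score
#' normalization stage: using QC rows only keeps biological cell-to-cell
#' variation out of the normalization parameters, so the resulting scale
#' reflects technical fluctuation.
#'
#' @param ds an \code{sc_dataset} with at least two QC rows (in \code{scope},
#'   per batch when \code{scope = "per_batch"}).
#' @param scope \code{"pooled"} (statistics over all QC samples, the default)
#'   or \code{"per_batch"} (separate statistics per batch).
#' @param sd_denominator \code{"n-1"} (sample standard deviation, default) or
#'   \code{"n"}.
#' @return An object of class \code{qc_stats}: for pooled scope a list with
#'   \code{mu}, \code{sigma} (named numeric vectors over features) and
#'   \code{n_qc}; for per-batch scope the same per batch under
#'   \code{$batches}, plus \code{scope}.
#' @export
compute_qc_stats <- function(ds, scope = c("pooled", "per_batch"),
                             sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(ds, "sc_dataset"))
  scope <- match.arg(scope)
  sd_denominator <- match.arg(sd_denominator)
  one <- function(rows) {
    n <- length(rows)
    if (n < 2L)
      stop("need at least 2 QC samples to compute QC statistics (got ", n, ")")
    x <- ds$intensities[rows, , drop = FALSE]
    mu <- colMeans(x)
    sigma <- apply(x, 2L, stats::sd)
    if (sd_denominator == "n") sigma <- sigma * sqrt((n - 1) / n)
    list(mu = mu, sigma = sigma, n_qc = n)
  }
  qc_rows <- which(ds$meta$role == "qc")
  if (scope == "pooled") {
    out <- one(qc_rows)
    out$scope <- "pooled"
  } else {
    batches <- unique(ds$meta$batch)
    per <- lapply(batches, function(b) one(qc_rows[ds$meta$batch[qc_rows] == b]))
    names(per) <- batches
    out <- list(batches = per, scope = "per_batch",
                n_qc = sum(vapply(per, `[[`, 0, "n_qc")))
  }
  structure(out, class = "qc_stats")
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("qc_stats (%s): %d QC samples\n", x$scope, x$n_qc))
  invisible(x)
}

# mu/sigma matrices aligned to the rows of ds (handles per-batch scope).
stats_per_row <- function(ds, stats) {
  n <- nrow(ds$intensities)
  if (stats$scope == "pooled") {
    p <- length(stats$mu)
    list(mu = matrix(stats$mu, n, p, byrow = TRUE),
         sigma = matrix(stats$sigma, n, p, byrow = TRUE))
  } else {
    miss <- setdiff(unique(ds$meta$batch), names(stats$batches))
    if (length(miss))
      stop("no QC statistics for batch(es): ", paste(miss, collapse = ", "))
    p <- length(stats$batches[[1L]]$mu)
    mu <- sig <- matrix(NA_real_, n, p)
    for (b in names(stats$batches)) {
      rows <- ds$meta$batch == b
      mu[rows, ] <- matrix(stats$batches[[b]]$mu, sum(rows), p, byrow = TRUE)
      sig[rows, ] <- matrix(stats$batches[[b]]$sigma, sum(rows), p, byrow = TRUE)
    }
    list(mu = mu, sigma = sig)
  }
}

stats_feature_ids <- function(stats) {
  if (stats$scope == "pooled") names(stats$mu) else names(stats$batches[[1L]]$mu)
}

#' Z-score normalization against QC statistics
#'
#' Transforms every intensity to \eqn{z_{ij} = (x_{ij} - \mu_j) / \sigma_j},
#' with \eqn{\mu_j}, \eqn{\sigma_j} computed on QC samples only
#' (\code{\link{compute_qc_stats}}). On the resulting scale QC rows have
#' per-feature mean 0 and standard deviation 1, so deviations measure
#' technical fluctuation in units of QC spread.
#'
#' Features with \eqn{\sigma_j = 0} carry no calibratable drift signal; by
#' default they are dropped (and recorded in \code{dropped_features}); with
#' \code{sigma_policy = "epsilon"} their \eqn{\sigma} is floored at a tiny
#' positive value instead.
#'
#' @param ds an \code{sc_dataset}.
#' @param stats a \code{qc_stats}, computed on the same feature set.
#' @param sigma_policy \code{"drop"} (default) or \code{"epsilon"}.
#' @return An object of class \code{zscored_table}: list with \code{z}
#'   (matrix, same row order as \code{ds}), \code{stats},
#'   \code{dropped_features} (character vector), \code{meta} and
#'   \code{features} carried along for the retained features.
#' @export
zscore_transform <- function(ds, stats = compute_qc_stats(ds),
                             sigma_policy = c("drop", "epsilon")) {
  stopifnot(inherits(ds, "sc_dataset"), inherits(stats, "qc_stats"))
  sigma_policy <- match.arg(sigma_policy)
  ids <- stats_feature_ids(stats)
  if (!identical(ids, colnames(ds$intensities)))
    stop("feature sets of dataset and QC statistics differ")
  sr <- stats_per_row(ds, stats)
  zero_sigma <- apply(sr$sigma, 2L, function(s) any(s == 0))
  dropped <- character(0)
  keep <- rep(TRUE, ncol(ds$intensities))
  if (any(zero_sigma)) {
    if (sigma_policy == "drop") {
      dropped <- colnames(ds$intensities)[zero_sigma]
      keep <- !zero_sigma
      message(length(dropped), " feature(s) with zero QC standard deviation dropped")
    } else {
      stats <- floor_stats(stats)  # floored sigma must survive into the inverse
      sr <- stats_per_row(ds, stats)
      message(sum(zero_sigma), " feature(s) with zero QC standard deviation floored at epsilon")
    }
  }
  z <- (ds$intensities[, keep, drop = FALSE] - sr$mu[, keep, drop = FALSE]) /
    sr$sigma[, keep, drop = FALSE]
  stats_kept <- subset_stats(stats, keep)
  structure(list(z = z, stats = stats_kept, dropped_features = dropped,
                 meta = ds$meta, features = ds$features[keep, , drop = FALSE]),
            class = "zscored_table")
}

# Replace zero sigmas by a machine-epsilon-scaled floor (epsilon policy).
floor_stats <- function(stats) {
  fl <- function(mu, sigma) {
    f <- .Machine$double.eps * pmax(abs(mu), 1)
    ifelse(sigma == 0, f, sigma)
  }
  if (stats$scope == "pooled") {
    stats$sigma <- fl(stats$mu, stats$sigma)
  } else {
    stats$batches <- lapply(stats$batches, function(b) {
      b$sigma <- fl(b$mu, b$sigma); b
    })
  }
  stats
}

subset_stats <- function(stats, keep) {
  if (stats$scope == "pooled") {
    stats$mu <- stats$mu[keep]
    stats$sigma <- stats$sigma[keep]
  } else {
    stats$batches <- lapply(stats$batches, function(b) {
      b$mu <- b$mu[keep]; b$sigma <- b$sigma[keep]; b
    })
  }
  stats
}

#' @export
print.zscored_table <- function(x, ...) {
  cat(sprintf("zscored_table: %d samples x %d features (%d dropped, sigma = 0)\n",
              nrow(x$z), ncol(x$z), length(x$dropped_features)))
  invisible(x)
}

#' Back-transform Z-scores to the raw intensity scale
#'
#' Inverts \code{\link{zscore_transform}}: \eqn{\hat x_{ij} = z_{ij} \sigma_j
#' + \mu_j}. Drift correction can legitimately push low signals below
#' \eqn{\mu - k\sigma}, so negative back-transformed values are clipped to 0
#' (intensities are non-negative by construction) and the number of clipped
#' cells is reported via a message and the \code{"n_clipped"} attribute.
#'
#' @param z a \code{zscored_table} (carrying its own QC statistics).
#' @param meta metadata aligned to the rows of \code{z} (defaults to the
#'   metadata carried in \code{z}); required to resolve per-batch statistics.
#' @return a \code{feature_table} on the raw intensity scale, with attribute
#'   \code{n_clipped}.
#' @export
inverse_zscore <- function(z, meta = z$meta) {
  stopifnot(inherits(z, "zscored_table"))
  ds_like <- structure(list(intensities = z$z, meta = meta), class = "sc_dataset")
  sr <- stats_per_row(ds_like, z$stats)
  x <- z$z * sr$sigma + sr$mu
  n_clipped <- sum(x < 0)
  if (n_clipped > 0) {
    message(n_clipped, " negative back-transformed intensit",
            if (n_clipped == 1) "y" else "ies", " clipped to 0")
    x[x < 0] <- 0
  }
  out <- new_feature_table(x, z$features)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Total-ion (total area per pixel) normalization
#'
#' The conventional ToF-SIMS baseline: each sample's feature intensities are
#' divided by that sample's total ion signal (row sum), so every output row
#' sums to one. Serves as the comparison method for the QC-driven correction.
#'
#' @param ds an \code{sc_dataset} (or \code{feature_table}).
#' @return object of the same class with row-normalized intensities.
#' @export
total_area_normalize <- function(ds) {
  stopifnot(inherits(ds, c("sc_dataset", "feature_table")))
  m <- ds$intensities
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("sample(s) with zero total intensity: ",
         paste(rownames(m)[rs == 0], collapse = ", "))
  ds$intensities <- m / rs
  ds
}
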