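#' @export
print.norm_svr_fit <- function(x, ...) {
  cat("QC-driven Norm-SVR drift correction\n\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  n_qc <- sum(x$corrected$meta$role == "qc")
  cat(sprintf("%d samples (%d cells, %d QC), %d features retained",
              nrow(x$corrected$intensities),
              nrow(x$corrected$intensities) - n_qc, n_qc,
              ncol(x$corrected$intensities)))
  if (length(x$dropped_features))
    cat(sprintf(" (%d dropped, zero QC variance)", length(x$dropped_features)))
  cat("\n")
  cat(sprintf("Drift models: %s scope, %s kernel, %d-fold CV\n",
              x$models$scope, x$config$kernel, x$config$cv_folds))
  cat(sprintf("Median QC RSD: %.1f%% -> %.1f%%\n",
              stats::median(x$diagnostics$qc_rsd_before),
              stats::median(x$diagnostics$qc_rsd_after)))
  invisible(x)
}

#' Summarize a fitted Norm-SVR correction
#'
#' @param object a \code{norm_svr_fit}.
#' @param rsd_threshold RSD threshold (percent) for the reported
#'   fraction-below summaries (default 30).
#' @param ... unused.
#' @return object of class \code{summary.norm_svr_fit} (printed summary of QC
#'   RSD improvement, chosen hyperparameters, and drift magnitude).
#' @export
summary.norm_svr_fit <- function(object, rsd_threshold = 30, ...) {
  d <- object$diagnostics
  fin <- is.finite(d$qc_rsd_before) & is.finite(d$qc_rsd_after)
  hyper <- coef(object)
  out <- list(
    n_features = nrow(d),
    rsd_threshold = rsd_threshold,
    median_before = stats::median(d$qc_rsd_before[fin]),
    median_after = stats::median(d$qc_rsd_after[fin]),
    frac_below_before = mean(d$qc_rsd_before[fin] < rsd_threshold),
    frac_below_after = mean(d$qc_rsd_after[fin] < rsd_threshold),
    frac_improved = mean(d$qc_rsd_after[fin] < d$qc_rsd_before[fin]),
    mean_abs_drift = mean(abs(object$drift)),
    cost_table = table(hyper$cost),
    epsilon_table = table(hyper$epsilon),
    n_clipped = object$n_clipped,
    config = object$config)
  class(out) <- "summary.norm_svr_fit"
  out
}

#' @export
print.summary.norm_svr_fit <- function(x, ...) {
  cat("Norm-SVR correction summary\n")
  cat(sprintf("  features: %d\n", x$n_features))
  cat(sprintf("  median QC RSD: %.2f%% -> %.2f%%\n",
              x$median_before, x$median_after))
  cat(sprintf("  fraction of features with QC RSD < %g%%: %.3f -> %.3f\n",
              x$rsd_threshold, x$frac_below_before, x$frac_below_after))
  cat(sprintf("  QC RSD improved for %.1f%% of features\n",
              100 * x$frac_improved))
  cat(sprintf("  mean |predicted drift|: %.3f (z units)\n", x$mean_abs_drift))
  cat("  chosen cost values:\n")
  print(x$cost_table)
  cat("  chosen epsilon values:\n")
  print(x$epsilon_table)
  if (x$n_clipped > 0)
    cat(sprintf("  %d corrected intensit%s clipped at 0\n", x$n_clipped,
                if (x$n_clipped == 1) "y" else "ies"))
  invisible(x)
}

#' Per-feature hyperparameter audit of a fitted correction
#'
#' @param object a \code{norm_svr_fit}.
#' @param ... unused.
#' @return data frame with one row per (feature, fitting unit): chosen cost,
#'   epsilon, gamma (and its grid label) and the cross-validated mean squared
#'   error.
#' @export
coef.norm_svr_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(object$models$units, `[[`, "hyper"))
  rownames(out) <- NULL
  out
}

#' @export
fitted.norm_svr_fit <- function(object, ...) object$drift

#' Corrected z-scores of a fitted Norm-SVR correction
#'
#' The residuals of the drift fit are the corrected data: what remains after
#' the predicted technical-error surface is subtracted from the z-scored
#' intensities.
#'
#' @param object a \code{norm_svr_fit}.
#' @param ... unused.
#' @return matrix of corrected z-scores (samples x features).
#' @export
residuals.norm_svr_fit <- function(object, ...) object$corrected_z$z

#' Predict the drift surface at new acquisition covariates
#'
#' @param object a \code{norm_svr_fit}.
#' @param newdata metadata data frame (\code{sample_id}, \code{role},
#'   \code{batch}, \code{region}, \code{acq_order}); defaults to the training
#'   metadata. Batch or region levels unseen during fitting are an error.
#' @param ... unused.
#' @return matrix of predicted drift (z units), rows matching \code{newdata}.
#' @export
predict.norm_svr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$drift)
  predict_drift(object$models, newdata)
}

#' Diagnostic plots for a fitted Norm-SVR correction
#'
#' Two panels: the per-feature QC RSD empirical cumulative distribution
#' before and after correction, and (when the fit retains more than one
#' sample per feature) the predicted drift of the worst-drifting feature over
#' acquisition order.
#'
#' @param x a \code{norm_svr_fit}.
#' @param ... passed to \code{plot.ecdf}.
#' @export
plot.norm_svr_fit <- function(x, ...) {
  d <- x$diagnostics
  fin <- is.finite(d$qc_rsd_before) & is.finite(d$qc_rsd_after)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lim <- range(0, pmin(d$qc_rsd_before[fin], 200), pmin(d$qc_rsd_after[fin], 200))
  plot(stats::ecdf(pmin(d$qc_rsd_before[fin], 200)), col = "grey40",
       main = "QC RSD", xlab = "RSD (%)", ylab = "cumulative fraction",
       xlim = lim, ...)
  graphics::lines(stats::ecdf(pmin(d$qc_rsd_after[fin], 200)), col = "firebrick")
  graphics::legend("bottomright", legend = c("before", "after"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  worst <- which.max(abs(apply(x$drift, 2L, function(v) diff(range(v)))))
  ord <- order(x$corrected$meta$batch, x$corrected$meta$acq_order)
  plot(seq_along(ord), x$drift[ord, worst], type = "p", pch = 16, cex = 0.6,
       xlab = "acquisition position", ylab = "predicted drift (z units)",
       main = colnames(x$drift)[worst])
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
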