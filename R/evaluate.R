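#' Per-feature relative standard deviation summary
#'
#' Computes, for the rows of one role (QC or cell), each feature's RSD
#' \eqn{100 \cdot sd_j / mean_j} (sample standard deviation, n-1
#' denominator). Low QC RSD is the primary repeatability diagnostic: QC
#' samples share one reference profile, so their spread is purely technical.
#' Features whose mean over the selected rows is 0 have undefined RSD; they
#' are assigned \code{Inf}, listed in \code{zero_mean_features}, and excluded
#' from the denominators of \code{\link{fraction_below}}.
#'
#' @param ds an \code{sc_dataset}.
#' @param role \code{"qc"} or \code{"cell"}.
#' @param bin_width histogram bin width in percent (default 10).
#' @param bin_max upper edge of the regular histogram range (default 200);
#'   larger finite RSDs fall in one overflow bin.
#' @return object of class \code{rsd_summary}: \code{rsd} (named vector,
#'   percent), \code{role}, \code{n_rows}, \code{zero_mean_features},
#'   \code{breaks}, \code{counts} (including the overflow bin), and
#'   \code{cumulative} (fraction of finite-RSD features at or below each
#'   break).
#' @export
compute_rsd <- function(ds, role = c("qc", "cell"), bin_width = 10, bin_max = 200) {
  stopifnot(inherits(ds, "sc_dataset"))
  role <- match.arg(role)
  rows <- which(ds$meta$role == role)
  if (length(rows) < 2L)
    stop("need at least 2 rows of role '", role, "' (got ", length(rows), ")")
  m <- ds$intensities[rows, , drop = FALSE]
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  rsd <- ifelse(mu == 0, Inf, 100 * s / mu)
  names(rsd) <- colnames(m)
  zero_mean <- colnames(m)[mu == 0]
  fin <- rsd[is.finite(rsd)]
  breaks <- seq(0, bin_max, by = bin_width)
  in_range <- fin[fin < bin_max]
  counts <- c(if (length(in_range))
                graphics::hist(in_range, breaks = breaks, right = FALSE,
                               plot = FALSE)$counts
              else integer(length(breaks) - 1L),
              sum(fin >= bin_max))  # trailing overflow bin
  cumulative <- if (length(fin)) vapply(breaks, function(b) mean(fin <= b), 0)
                else rep(NA_real_, length(breaks))
  structure(list(rsd = rsd, role = role, n_rows = length(rows),
                 zero_mean_features = zero_mean, breaks = breaks,
                 counts = counts, cumulative = cumulative),
            class = "rsd_summary")
}

#' @export
print.rsd_summary <- function(x, ...) {
  fin <- x$rsd[is.finite(x$rsd)]
  cat(sprintf("rsd_summary (%s rows, n = %d): %d features", x$role, x$n_rows,
              length(x$rsd)))
  if (length(x$zero_mean_features))
    cat(sprintf(" (%d zero-mean, RSD undefined)", length(x$zero_mean_features)))
  cat(sprintf("\n  median %.1f%%; fraction < 30%%: %.3f\n",
              stats::median(fin), mean(fin < 30)))
  invisible(x)
}

#' Fraction of features below an RSD threshold
#'
#' Strict inequality; features with undefined (infinite) RSD are excluded
#' from the denominator.
#'
#' @param summary an \code{rsd_summary} (or bare numeric RSD vector, percent).
#' @param threshold_pct positive threshold in percent.
#' @return fraction in [0, 1].
#' @export
fraction_below <- function(summary, threshold_pct) {
  if (threshold_pct <= 0) stop("threshold must be positive")
  rsd <- if (inherits(summary, "rsd_summary")) summary$rsd else summary
  fin <- rsd[is.finite(rsd)]
  if (!length(fin)) return(NA_real_)
  mean(fin < threshold_pct)
}

#' Principal component analysis of a feature table
#'
#' Columns are mean-centered and, by default, scaled to unit variance
#' (correlation PCA) — without a fixed scaling convention, comparisons
#' between raw and normalized tables are dominated by arbitrary intensity
#' units. Component signs are fixed by making each component's
#' largest-magnitude loading positive, so results are reproducible across
#' platforms. When scaling, zero-variance features are removed with a
#' message (they carry no direction).
#'
#' @param ds an \code{sc_dataset} or \code{feature_table}.
#' @param scale_features scale columns to unit variance (default TRUE).
#' @param n_components number of components to retain in \code{scores}
#'   (default: all).
#' @return object of class \code{pca_result}: \code{scores} (samples x
#'   components), \code{loadings}, \code{explained_variance_pct} (over the
#'   full decomposition), \code{preprocessing}.
#' @export
run_pca <- function(ds, scale_features = TRUE, n_components = NULL) {
  m <- ds$intensities
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("PCA needs at least 3 samples and 2 features")
  v <- apply(m, 2L, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose")
  if (scale_features && any(v == 0)) {
    message(sum(v == 0), " zero-variance feature(s) removed before scaled PCA")
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale_features)
  ev <- pc$sdev^2
  ev_pct <- 100 * ev / sum(ev)
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  k <- if (is.null(n_components)) ncol(scores) else min(n_components, ncol(scores))
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 loadings = loadings[, seq_len(k), drop = FALSE],
                 explained_variance_pct = ev_pct,
                 preprocessing = list(center = TRUE, scale = scale_features)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components retained\n",
              nrow(x$scores), ncol(x$scores)))
  k <- min(3L, length(x$explained_variance_pct))
  cat("  explained variance (%):",
      paste(sprintf("PC%d %.2f", seq_len(k), x$explained_variance_pct[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Correlation and rank-preservation report
#'
#' Quantifies what a correction changed and what it preserved: the Pearson
#' sample-by-sample correlation matrix of the corrected table (block
#' structure here reveals residual region/batch effects), the per-sample
#' Spearman correlation between each sample's feature vector before and
#' after correction (rank preservation: values near 1 mean the within-cell
#' intensity ordering survived), group-wise medians of those Spearman values,
#' and a least-squares fit of log10 per-sample mean intensity after vs
#' before.
#'
#' @param before an \code{sc_dataset} (e.g. raw data).
#' @param after an \code{sc_dataset} with identical samples and features.
#' @return object of class \code{correlation_report}: \code{pearson} (matrix),
#'   \code{per_sample_spearman} (named vector), \code{group_summaries}
#'   (data frame of medians by region, batch and role), \code{log10_fit}
#'   (slope, intercept, r_squared, n).
#' @export
correlation_report <- function(before, after) {
  mb <- before$intensities; ma <- after$intensities
  if (!identical(dim(mb), dim(ma)) ||
      !identical(rownames(mb), rownames(ma)) ||
      !identical(colnames(mb), colnames(ma)))
    stop("before/after tables must share samples and features")
  pearson <- stats::cor(t(ma))
  sp <- vapply(seq_len(nrow(mb)), function(i)
    stats::cor(mb[i, ], ma[i, ], method = "spearman"), 0)
  names(sp) <- rownames(mb)
  meta <- before$meta
  group_summaries <- NULL
  if (!is.null(meta)) {
    grp <- ifelse(meta$role == "qc", "QC", paste0("region_", meta$region))
    gs1 <- stats::aggregate(sp, list(group = grp), stats::median)
    grp2 <- ifelse(meta$role == "qc", "QC", paste0("batch_", meta$batch))
    gs2 <- stats::aggregate(sp, list(group = grp2), stats::median)
    group_summaries <- unique(rbind(gs1, gs2))
    names(group_summaries)[2L] <- "median_spearman"
  }
  mean_b <- rowMeans(mb); mean_a <- rowMeans(ma)
  pos <- mean_b > 0 & mean_a > 0
  if (any(!pos))
    warning(sum(!pos), " sample(s) with zero mean intensity excluded from log10 fit",
            call. = FALSE)
  fit <- stats::lm(log10(mean_a[pos]) ~ log10(mean_b[pos]))
  # suppressWarnings: summary.lm warns on an exactly perfect fit, which is
  # the expected outcome when before == after
  log10_fit <- list(slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    r_squared = suppressWarnings(summary(fit)$r.squared),
                    n = sum(pos))
  structure(list(pearson = pearson, per_sample_spearman = sp,
                 group_summaries = group_summaries, log10_fit = log10_fit),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d samples\n", nrow(x$pearson)))
  cat(sprintf("  median per-sample Spearman (before vs after): %.4f\n",
              stats::median(x$per_sample_spearman)))
  cat(sprintf("  log10 mean-intensity fit: slope %.3f, R^2 %.3f\n",
              x$log10_fit$slope, x$log10_fit$r_squared))
  invisible(x)
}

#' LOESS trend of one feature ion over the acquisition sequence
#'
#' Local linear regression (degree 1, tricube weights, no robustness
#' iterations) of one feature's intensity against acquisition order or plain
#' sample index, evaluated at every observed covariate value — the smoothed
#' trend lines used to visualize per-ion signal drift.
#'
#' @param ds an \code{sc_dataset}.
#' @param feature feature id.
#' @param by \code{"acq_order"} (default; rows ordered by batch then order)
#'   or \code{"sample_index"}.
#' @param span LOESS span (default 0.75).
#' @param role optional role filter (\code{"cell"} or \code{"qc"}); default
#'   uses all rows.
#' @return data frame with \code{x}, \code{y} (observed) and \code{trend}
#'   (smoothed), ordered by \code{x}.
#' @export
loess_trend <- function(ds, feature, by = c("acq_order", "sample_index"),
                        span = 0.75, role = NULL) {
  stopifnot(inherits(ds, "sc_dataset"))
  by <- match.arg(by)
  if (!feature %in% colnames(ds$intensities))
    stop("feature not found: ", feature)
  rows <- seq_len(nrow(ds$intensities))
  if (!is.null(role)) rows <- rows[ds$meta$role[rows] == role]
  if (length(rows) < 5L) stop("need at least 5 points for a LOESS trend")
  x <- if (by == "acq_order") {
    ord <- order(ds$meta$batch[rows], ds$meta$acq_order[rows])
    rows <- rows[ord]
    seq_along(rows)
  } else seq_along(rows)
  y <- ds$intensities[rows, feature]
  fit <- stats::loess(y ~ x, degree = 1, span = span, family = "gaussian",
                      surface = "direct")
  data.frame(sample_id = ds$meta$sample_id[rows], x = x, y = y,
             trend = stats::predict(fit, data.frame(x = x)),
             stringsAsFactors = FALSE)
}

#' Silhouette-based batch/region mixing score
#'
#' Mean silhouette coefficient of the given labels on the first two principal
#' component scores (Euclidean distance) — a scalar version of what a reader
#' judges from a 2-D score plot. Values near 1 mean tight, well-separated
#' label clusters (a strong batch/region effect); values near 0 or below mean
#' the labels are mixed.
#'
#' @param pca a \code{pca_result} with at least 2 components.
#' @param labels vector of batch/region labels, one per sample.
#' @return mean silhouette width in [-1, 1] (lower = better mixed).
#' @export
batch_mixing_score <- function(pca, labels) {
  stopifnot(inherits(pca, "pca_result"))
  labels <- as.character(labels)
  if (length(labels) != nrow(pca$scores))
    stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2L) stop("at least 2 label groups required")
  if (any(tab < 2L)) stop("every label group needs at least 2 samples")
  xy <- pca$scores[, 1:2, drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(xy))
  mean(sil[, "sil_width"])
}

#' Write a full evaluation report directory
#'
#' Computes the complete diagnostic battery comparing a table before and
#' after correction and writes it as CSV files plus PNG figures: QC and cell
#' RSD summaries, PCA scores and explained variance (on the after table),
#' the Pearson sample correlation matrix, per-sample Spearman rank
#' preservation, and the log10 mean-intensity fit.
#'
#' @param before an \code{sc_dataset}.
#' @param after an \code{sc_dataset}, same samples/features.
#' @param out_dir output directory (created if needed).
#' @param figures also render PNG figures (default TRUE).
#' @return (invisibly) named list of the computed objects.
#' @export
evaluation_report <- function(before, after, out_dir, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rsd_qc <- compute_rsd(after, "qc")
  rsd_cell <- compute_rsd(after, "cell")
  pca <- run_pca(after)
  corr <- correlation_report(before, after)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  rsd_df <- function(s) data.frame(feature_id = names(s$rsd),
                                   rsd_pct = unname(s$rsd),
                                   stringsAsFactors = FALSE)
  wr(rsd_df(rsd_qc), "rsd_qc.csv")
  wr(rsd_df(rsd_cell), "rsd_cell.csv")
  wr(data.frame(sample_id = rownames(pca$scores),
                pca$scores[, seq_len(min(5L, ncol(pca$scores))), drop = FALSE]),
     "pca_scores.csv")
  wr(data.frame(component = seq_along(pca$explained_variance_pct),
                explained_variance_pct = pca$explained_variance_pct),
     "pca_variance.csv")
  utils::write.csv(as.data.frame(corr$pearson), file.path(out_dir, "pearson.csv"))
  wr(data.frame(sample_id = names(corr$per_sample_spearman),
                spearman = unname(corr$per_sample_spearman)),
     "spearman_per_sample.csv")
  wr(as.data.frame(corr$log10_fit), "log10_fit.csv")
  wr(corr$group_summaries, "spearman_by_group.csv")
  if (figures) {
    grDevices::png(file.path(out_dir, "rsd_ecdf.png"), 900, 450)
    op <- graphics::par(mfrow = c(1, 2))
    for (s in list(rsd_qc, rsd_cell)) {
      fin <- pmin(s$rsd[is.finite(s$rsd)], 200)
      plot(stats::ecdf(fin), main = paste("RSD,", s$role, "samples"),
           xlab = "RSD (%)", ylab = "cumulative fraction")
      graphics::abline(v = 30, lty = 3)
    }
    graphics::par(op)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "pca_scores.png"), 600, 550)
    lab <- if (!is.null(after$meta))
      ifelse(after$meta$role == "qc", "QC", after$meta$batch) else "sample"
    cols <- as.integer(factor(lab))
    plot(pca$scores[, 1], pca$scores[, 2], col = cols, pch = 16,
         xlab = sprintf("PC1 (%.1f%%)", pca$explained_variance_pct[1]),
         ylab = sprintf("PC2 (%.1f%%)", pca$explained_variance_pct[2]),
         main = "PCA scores")
    graphics::legend("topright", legend = levels(factor(lab)),
                     col = seq_along(levels(factor(lab))), pch = 16, bty = "n")
    grDevices::dev.off()
  }
  invisible(list(rsd_qc = rsd_qc, rsd_cell = rsd_cell, pca = pca,
                 correlation = corr))
}
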