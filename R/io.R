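#' Read a single-cell feature table
#'
#' Reads a samples-by-features intensity table from CSV or TSV. The first
#' column holds sample identifiers; the header row holds feature identifiers,
#' either of the form \code{"mz_<value>"} or plain numeric m/z values.
#' Intensities are raw-scale per-cell ion areas or summed counts and must be
#' non-negative and finite.
#'
#' Feature annotations (m/z, polarity, total signal counts, signal-to-noise
#' ratio) may be supplied through a side-car feature file (see
#' \code{read_features}). When absent, \code{total_counts} defaults to the
#' column sum of the table and \code{snr} to \code{Inf}, so that
#' \code{\link{filter_peaks}} passes vacuously on those attributes; a warning
#' records the fallback, since peak screening is ordinarily performed upstream
#' in vendor software.
#'
#' @param path path to the table file.
#' @param format \code{"csv"} (comma separator) or \code{"tsv"} (tab).
#' @param features optional feature annotation data frame with columns
#'   \code{feature_id}, \code{mz}, \code{polarity}, \code{total_counts},
#'   \code{snr}, typically from \code{read_features}.
#' @return An object of class \code{feature_table}: a list with
#'   \code{intensities} (numeric matrix, samples x features, dimnames set) and
#'   \code{features} (annotation data frame, one row per feature).
#' @seealso \code{\link{read_metadata}}, \code{\link{join_dataset}},
#'   \code{\link{filter_peaks}}, \code{\link{write_feature_table}}
#' @export
read_feature_table <- function(path, format = c("csv", "tsv"), features = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L)
    stop("feature table needs a sample-id column plus at least one feature column")
  sample_ids <- raw[[1L]]
  feature_ids <- colnames(raw)[-1L]
  mat <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw))))
  if (nrow(raw) == 1L) mat <- matrix(mat, nrow = 1L)
  bad <- which(is.na(mat) | !is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "invalid intensity at sample '%s', feature '%s': '%s' (must be a finite non-negative number)",
      sample_ids[i], feature_ids[j], raw[i, j + 1L]))
  }
  dimnames(mat) <- list(sample_ids, feature_ids)
  if (is.null(features))
    warning("no feature annotations supplied: total_counts set to column sums, ",
            "snr to Inf (peak filter passes vacuously on snr)", call. = FALSE)
  new_feature_table(mat, features)
}

#' Construct a feature table from an intensity matrix
#'
#' Programmatic counterpart of \code{\link{read_feature_table}}: validates an
#' intensity matrix (dimnames = sample and feature ids) and optional feature
#' annotations into a \code{feature_table}. Without annotations,
#' \code{total_counts} defaults to column sums and \code{snr} to \code{Inf}.
#'
#' @param intensities numeric matrix, samples x features, with dimnames.
#' @param features optional annotation data frame (columns \code{feature_id},
#'   \code{mz}, \code{polarity}, \code{total_counts}, \code{snr}).
#' @return a \code{feature_table}.
#' @export
feature_table <- function(intensities, features = NULL) {
  new_feature_table(intensities, features)
}

#' Read a side-car feature annotation file
#'
#' @param path CSV/TSV with columns \code{feature_id}, \code{mz},
#'   \code{polarity}, \code{total_counts}, \code{snr} (case-insensitive).
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return data frame suitable for the \code{features} argument of
#'   \code{\link{read_feature_table}}.
#' @export
read_features <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("feature_id", "mz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature file missing column(s): ", paste(miss, collapse = ", "))
  df$feature_id <- as.character(df$feature_id)
  df$mz <- as.numeric(df$mz)
  if (is.null(df$polarity)) df$polarity <- NA_character_
  if (is.null(df$total_counts)) df$total_counts <- NA_real_
  if (is.null(df$snr)) df$snr <- NA_real_
  df[c("feature_id", "mz", "polarity", "total_counts", "snr")]
}

# Construct + validate the feature_table container. `features` may be NULL
# (annotations derived from the matrix), or a data.frame keyed by feature_id.
new_feature_table <- function(intensities, features = NULL) {
  stopifnot(is.matrix(intensities))
  sample_ids <- rownames(intensities)
  feature_ids <- colnames(intensities)
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("intensity matrix must carry sample ids (rownames) and feature ids (colnames)")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(features)) {
    features <- data.frame(
      feature_id = feature_ids,
      mz = parse_mz(feature_ids),
      polarity = NA_character_,
      total_counts = unname(colSums(intensities)),
      snr = Inf,
      stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(feature_ids, features$feature_id)
    if (length(miss))
      stop("feature(s) missing from annotations: ", paste(utils::head(miss, 5), collapse = ", "))
    features <- features[match(feature_ids, features$feature_id), , drop = FALSE]
    rownames(features) <- NULL
    if (anyNA(features$total_counts)) {
      idx <- is.na(features$total_counts)
      features$total_counts[idx] <- colSums(intensities)[idx]
    }
    if (anyNA(features$snr)) features$snr[is.na(features$snr)] <- Inf
    if (any(features$mz < 0, na.rm = TRUE)) stop("m/z values must be >= 0")
    if (any(features$total_counts < 0)) stop("total_counts must be >= 0")
    if (any(features$snr < 0)) stop("snr must be >= 0")
  }
  structure(list(intensities = intensities, features = features),
            class = "feature_table")
}

# "mz_184.07" or "184.07" -> 184.07; anything unparsable -> NA
parse_mz <- function(ids) {
  x <- sub("^mz_", "", ids)
  suppressWarnings(as.numeric(x))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  rng <- range(x$features$mz, na.rm = TRUE)
  if (all(is.finite(rng)))
    cat(sprintf("  m/z range: %.3f - %.3f\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Write a feature table to CSV/TSV
#'
#' Mirrors the input dialect of \code{\link{read_feature_table}}: header row
#' \code{sample_id} followed by feature ids, one row per sample. Values are
#' written with up to 12 significant digits so that a write/read round trip is
#' exact for such representations.
#'
#' @param table a \code{feature_table} (or an \code{sc_dataset}, whose table
#'   part is written).
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @export
write_feature_table <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(table, "sc_dataset")) table <- as_feature_table(table)
  sep <- if (format == "csv") "," else "\t"
  m <- table$intensities
  df <- data.frame(sample_id = rownames(m),
                   signif(m, 12), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns \code{sample_id}, \code{role}, \code{batch},
#' \code{region}, \code{acq_order} (case-insensitive). Roles are normalized to
#' lowercase \code{"cell"} / \code{"qc"}. Acquisition order is the 0-based
#' position within each batch's acquisition sequence; files using 1-based
#' order (detected by \code{min(acq_order) == 1}) are shifted down with a
#' message.
#'
#' @param path path to the metadata CSV/TSV.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return data frame with the five canonical columns.
#' @export
read_metadata <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  validate_metadata(df)
}

# Shared validation for metadata from file or constructed in code.
validate_metadata <- function(df) {
  need <- c("sample_id", "role", "batch", "region", "acq_order")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$role <- tolower(as.character(df$role))
  bad <- setdiff(unique(df$role), c("cell", "qc"))
  if (length(bad))
    stop("unknown role value(s): ", paste(bad, collapse = ", "),
         " (expected 'cell' or 'qc')")
  df$batch <- as.character(df$batch)
  df$region <- as.character(df$region)
  ord <- suppressWarnings(as.numeric(df$acq_order))
  if (anyNA(ord) || any(ord != floor(ord)) || any(ord < 0))
    stop("acq_order must be non-negative integers")
  if (min(ord) == 1) {
    message("acq_order appears 1-based (min == 1); shifting to 0-based")
    ord <- ord - 1
  }
  df$acq_order <- as.integer(ord)
  dup <- duplicated(df[c("batch", "acq_order")])
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicate acquisition position: batch '%s', acq_order %d",
                 d$batch, d$acq_order))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Filter feature ions by signal counts, SNR and mass range
#'
#' Retains features with \code{total_counts > min_counts} (strict, matching
#' the screening phrase "exceeding 1000"), \code{snr >= min_snr} (inclusive),
#' and \code{0 <= mz <= mz_max}. Features with unparsable m/z are kept (the
#' mass-range criterion cannot be evaluated for them) with a warning. Sample
#' rows and retained-feature order are unchanged; the filter is idempotent.
#'
#' @param table a \code{feature_table}.
#' @param min_counts strict lower bound on summed signal counts (default 1000).
#' @param min_snr inclusive lower bound on signal-to-noise ratio (default 3.0).
#' @param mz_max upper end of the instrument mass range in Da (default 824).
#' @return the filtered \code{feature_table}.
#' @export
filter_peaks <- function(table, min_counts = 1000, min_snr = 3.0, mz_max = 824) {
  stopifnot(inherits(table, "feature_table"))
  if (min_counts < 0 || min_snr < 0 || mz_max < 0)
    stop("thresholds must be >= 0")
  f <- table$features
  mz_ok <- is.na(f$mz) | (f$mz >= 0 & f$mz <= mz_max)
  if (anyNA(f$mz))
    warning(sum(is.na(f$mz)), " feature(s) lack a parsable m/z; mass-range filter skipped for them",
            call. = FALSE)
  keep <- f$total_counts > min_counts & f$snr >= min_snr & mz_ok
  if (!any(keep))
    stop("all features removed by peak filter; review min_counts/min_snr/mz_max thresholds")
  structure(list(intensities = table$intensities[, keep, drop = FALSE],
                 features = f[keep, , drop = FALSE]),
            class = "feature_table")
}

#' Join a feature table with sample metadata
#'
#' Matches rows by sample id and produces the canonical dataset all downstream
#' steps consume. The sample sets must coincide exactly and at least one QC
#' row must be present. Rows keep the feature table's order.
#'
#' @param table a \code{feature_table}.
#' @param meta metadata data frame as returned by \code{\link{read_metadata}}.
#' @return An object of class \code{sc_dataset}: list with \code{intensities}
#'   (matrix), \code{features} (annotation data frame) and \code{meta}
#'   (metadata aligned to the matrix rows).
#' @export
join_dataset <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"))
  meta <- validate_metadata(as.data.frame(meta))
  ids <- rownames(table$intensities)
  only_table <- setdiff(ids, meta$sample_id)
  only_meta <- setdiff(meta$sample_id, ids)
  if (length(only_table) || length(only_meta))
    stop("sample sets differ between table and metadata",
         if (length(only_table)) paste0("; missing from metadata: ",
                                        paste(only_table, collapse = ", ")),
         if (length(only_meta)) paste0("; missing from table: ",
                                       paste(only_meta, collapse = ", ")))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!any(meta$role == "qc"))
    stop("at least one QC sample required")
  structure(list(intensities = table$intensities,
                 features = table$features,
                 meta = meta),
            class = "sc_dataset")
}

#' Extract the feature table part of a dataset
#' @param ds an \code{sc_dataset}.
#' @return a \code{feature_table}.
#' @export
as_feature_table <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  structure(list(intensities = ds$intensities, features = ds$features),
            class = "feature_table")
}

#' @export
print.sc_dataset <- function(x, ...) {
  n_qc <- sum(x$meta$role == "qc")
  cat(sprintf("sc_dataset: %d samples (%d cells, %d QC) x %d features\n",
              nrow(x$intensities), nrow(x$intensities) - n_qc, n_qc,
              ncol(x$intensities)))
  cat(sprintf("  batches: %s; regions: %s\n",
              paste(unique(x$meta$batch), collapse = ", "),
              paste(unique(x$meta$region), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$intensities)

# Replace the intensity matrix of a dataset, keeping ids/annotations.
set_intensities <- function(ds, m) {
  stopifnot(identical(dim(m), dim(ds$intensities)))
  dimnames(m) <- dimnames(ds$intensities)
  ds$intensities <- m
  ds
}
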