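#' Encode acquisition covariates as a design matrix
#'
#' Builds the regression inputs for the drift models from sample metadata.
#' Acquisition order is scaled to [0, 1] within each batch (order divided by
#' the batch's maximum order), so sequences of different lengths share a
#' common time axis; region and batch become one-hot indicator columns.
#' Column order is deterministic: the scaled order column first, then region
#' levels sorted lexicographically, then batch levels sorted lexicographically.
#'
#' When \code{levels} (from a previous encoding) is supplied, the same columns
#' are reproduced and a region/batch level unseen in that encoding is an
#' error: drift models are never extrapolated across categorical levels they
#' were not fitted on.
#'
#' @param meta metadata data frame (\code{\link{read_metadata}} layout).
#' @param covariates non-empty subset of
#'   \code{c("acq_order", "region", "batch")}.
#' @param levels optional list with elements \code{region}, \code{batch} and
#'   \code{order_max} (named per batch) captured from a training encoding.
#' @return numeric design matrix, one row per metadata row, with a
#'   \code{"levels"} attribute recording the encoding.
#' @export
encode_covariates <- function(meta, covariates = c("acq_order", "region", "batch"),
                              levels = NULL) {
  if (length(covariates) == 0L)
    stop("at least one covariate required")
  bad <- setdiff(covariates, c("acq_order", "region", "batch"))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  meta <- as.data.frame(meta)
  n <- nrow(meta)
  cols <- list()
  if (is.null(levels)) {
    levels <- list(
      region = sort(unique(as.character(meta$region))),
      batch = sort(unique(as.character(meta$batch))),
      order_max = tapply(meta$acq_order, as.character(meta$batch), max))
  }
  if ("acq_order" %in% covariates) {
    bt <- as.character(meta$batch)
    miss <- setdiff(unique(bt), names(levels$order_max))
    if (length(miss))
      stop("batch level(s) unseen during fitting: ", paste(miss, collapse = ", "))
    omax <- pmax(unname(levels$order_max[bt]), 1L)
    cols$order_scaled <- meta$acq_order / omax
  }
  onehot <- function(vals, levs, what) {
    vals <- as.character(vals)
    miss <- setdiff(unique(vals), levs)
    if (length(miss))
      stop(what, " level(s) unseen during fitting: ", paste(miss, collapse = ", "))
    m <- vapply(levs, function(l) as.numeric(vals == l), numeric(length(vals)))
    if (length(vals) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, levs))
    colnames(m) <- paste0(what, "_", levs)
    m
  }
  X <- if (length(cols)) matrix(cols$order_scaled, n, 1L,
                                dimnames = list(NULL, "order_scaled")) else
    matrix(numeric(0), n, 0L)
  if ("region" %in% covariates)
    X <- cbind(X, onehot(meta$region, levels$region, "region"))
  if ("batch" %in% covariates)
    X <- cbind(X, onehot(meta$batch, levels$batch, "batch"))
  attr(X, "levels") <- levels
  attr(X, "covariates") <- covariates
  X
}
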