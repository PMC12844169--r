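# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdirs.

# Minimal dataset from an explicit intensity matrix and roles; batches,
# regions, acquisition order filled in deterministically.
make_dataset <- function(m, roles, batch = NULL, region = NULL,
                         acq_order = NULL) {
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(m))) colnames(m) <- sprintf("mz_%d", 100 + seq_len(ncol(m)))
  if (is.null(batch)) batch <- rep("b1", n)
  if (is.null(region)) region <- rep("r1", n)
  if (is.null(acq_order)) {
    acq_order <- integer(n)
    for (b in unique(batch))
      acq_order[batch == b] <- seq_len(sum(batch == b)) - 1L
  }
  meta <- data.frame(sample_id = rownames(m), role = roles, batch = batch,
                     region = region, acq_order = acq_order,
                     stringsAsFactors = FALSE)
  table <- suppressWarnings(normsvr:::new_feature_table(m, NULL))
  join_dataset(table, meta)
}

# A small but realistic simulated dataset reused across tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_tofsims(synthetic_config(
        n_cells_per_batch = 16L, n_batches = 2L, n_regions_per_batch = 2L,
        n_features = 20L, seed = 42L))
    cache
  }
})

# Fast correction configuration for tests that only need a working fit.
fast_config <- function(seed = 1L, ...)
  correction_config(c_grid = c(1, 100), epsilon_grid = 0.05,
                    gamma_grid = list("scale"), cv_folds = 3L, seed = seed, ...)
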