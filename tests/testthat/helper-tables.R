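# shared fixtures, built in code

.sim_cache <- new.env(parent = emptyenv())

# simulations are reused across tests that only read them
cached_sim <- function(seed = 1L, n_outlier_samples = 0L, ...) {
  key <- paste(seed, n_outlier_samples, ..., sep = "_")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(seed = seed, n_outlier_samples = n_outlier_samples, ...)
    .sim_cache[[key]] <- simulate_study(cfg = cfg)
  }
  .sim_cache[[key]]
}

# a small hand-specified table; species/batch vectors are recycled per sample
tiny_table <- function(m, roles = "study", species = NA, batch = "pos01",
                       convention = "NA", rt = NULL, mz = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  sm <- data.frame(sample_id = colnames(m),
                   role = rep_len(roles, ncol(m)),
                   species_code = rep_len(species, ncol(m)),
                   batch_id = rep_len(batch, ncol(m)),
                   stringsAsFactors = FALSE)
  fm <- data.frame(feature_id = rownames(m),
                   mz = if (is.null(mz)) rep(500, nrow(m)) else mz,
                   rt = if (is.null(rt)) rep(400, nrow(m)) else rt,
                   stringsAsFactors = FALSE)
  feature_table(m, sm, fm, missing_convention = convention)
}

# an all-missing table with exactly nr * nc cells, for imputation tests
blank_canvas <- function(nr, nc) {
  m <- matrix(NA_real_, nr, nc)
  tiny_table(m)
}
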