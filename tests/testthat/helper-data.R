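# Shared small synthetic datasets, built once per test run.

.tt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tt_cache)) assign(key, expr, envir = .tt_cache)
  get(key, envir = .tt_cache)
}

# small default-structure dataset (fast; for unit tests)
small_dataset <- function() {
  cached("small_ds", simulate_dataset(sim_config(cells_per_stage = 60,
                                                 seed = 101)))
}

# its QC'd + normalized expression and the PBA trajectory
small_pipeline <- function() {
  cached("small_pipe", {
    ds <- small_dataset()
    qc <- qc_filter(ds$counts, qc_params(min_genes = 50, max_genes = 4500))
    norm <- quantile_normalize(qc$matrix)
    res <- pba_trajectory(norm, ds$truth$marker_genes[c("CD4sp", "CD8sp")],
                          n_sinks = 5L)
    list(ds = ds, norm = norm, res = res,
         truth = ds$truth$cells[names(res$order), ])
  })
}
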