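# small in-code fixtures shared across test files

tiny_grid <- function(d = c(8, 8, 8)) voxel_grid(d, c(2, 2, 2))

full_mask <- function(grid) brain_mask(grid, array(TRUE, grid$dims))

# control-only two-scanner cohort at reduced voxel count
small_hc_spec <- function(seed, n_per_scanner = 25, dims = c(8, 8, 8),
                          batch_shift = NULL, batch_scale = NULL) {
  cohort_spec(dims = dims,
              n_hc = c(scannerA = n_per_scanner, scannerB = n_per_scanner),
              batch_shift = batch_shift, batch_scale = batch_scale,
              seed = seed)
}

# per-subject mean Z split by scanner after a given harmonization,
# using 2-fold cross-validated deviations of the control cohort
scanner_z_means <- function(sim, method, seed) {
  maps <- sim$maps
  covs <- build_design(sim$cohort, c("age", "sex"))$X[, -1, drop = FALSE]
  if (method == "combat") {
    fit <- fit_combat(maps, sim$cohort$scanner_id, covariates = covs)
    maps <- apply_combat(fit, maps, sim$cohort$scanner_id,
                         covariates = covs)
  } else if (method == "smoothing") {
    maps <- gaussian_smooth(maps, 3)
  }
  cv <- crossval_deviations(maps, sim$cohort, c("age", "sex"), k = 2,
                            seed = seed)
  split(rowMeans(cv$dev$Z, na.rm = TRUE), sim$cohort$scanner_id)
}
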