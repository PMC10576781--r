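# Shared fixtures generated in code.

test_geometry <- function(scans_per_line = 400L, n_lines = 1L,
                          probe_rate = 5, acquisition_rate = 2,
                          strip_step = 80) {
  scan_geometry(probe_rate, acquisition_rate, strip_step,
                scans_per_line, n_lines)
}

# A small, well-separated two-proteoform ion dataset with assigned charges.
two_proteoform_ions <- function(seed = 42L, budget1 = 3000, budget2 = 2000,
                                noise_rate = 0.2, calib = 12.5,
                                cv = 0.01) {
  geom <- test_geometry()
  specs <- dplyr::bind_rows(
    proteoform_spec("P1", 9000, budget1, charge_mu = 9, charge_sigma = 1,
                    spatial_profile = gaussian_profile(400, 0.3, 0.08)),
    proteoform_spec("P2", 12000, budget2, charge_mu = 11, charge_sigma = 1,
                    spatial_profile = gaussian_profile(400, 0.7, 0.1))
  )
  ds <- simulate_line_scan(specs, geom, calib_slope = calib,
                           noise_ion_rate = noise_rate, slope_noise_cv = cv,
                           seed = seed)
  set.seed(seed)
  ions <- assign_charge(ds$ions, calib)
  list(dataset = ds, ions = ions, geometry = geom, calib = calib)
}

# Long-format profile table for the bin allocator from a plain counts matrix
# (targets in rows).
profiles_from_matrix <- function(m, bin_um = 100) {
  targets <- rownames(m)
  out <- tidyr::expand_grid(feature_id = targets,
                            bin_index = seq_len(ncol(m)))
  out$count <- as.integer(t(m)[cbind(out$bin_index,
                                     match(out$feature_id, targets))])
  out$bin_start <- (out$bin_index - 1) * bin_um
  out$bin_end <- out$bin_index * bin_um
  attr(out, "bin_edges") <- seq(0, ncol(m) * bin_um, by = bin_um)
  out[, c("feature_id", "bin_index", "bin_start", "bin_end", "count")]
}

# Random smooth spatial profiles for allocator convergence runs.
random_profiles <- function(n_targets, n_bins, seed) {
  set.seed(seed)
  m <- matrix(0, n_targets, n_bins,
              dimnames = list(sprintf("T%03d", seq_len(n_targets)), NULL))
  x <- (seq_len(n_bins) - 0.5) / n_bins
  for (i in seq_len(n_targets)) {
    center <- stats::runif(1)
    width <- stats::runif(1, 0.03, 0.15)
    amp <- stats::rlnorm(1, log(200), 0.8)
    lam <- amp * (exp(-0.5 * ((x - center) / width)^2) + 0.02)
    m[i, ] <- stats::rpois(n_bins, lam)
  }
  m
}
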