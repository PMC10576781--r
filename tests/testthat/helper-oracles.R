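# Independent oracles: deliberately naive implementations used only to check
# the package's fast paths on small instances.

# Aggregated isotope distribution by brute-force atom-at-a-time polynomial
# convolution of the averagine elemental composition (no exponentiation
# tricks, no truncation other than `len`).
oracle_averagine_pmf <- function(mass, len = 64L) {
  comp <- averagine_composition(mass)
  elements <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9493, 0.0076, 0.0429, 0, 0.0002)
  )
  pmf <- 1
  for (el in names(comp)) {
    p <- elements[[el]]
    for (i in seq_len(comp[[el]])) {
      out <- numeric(min(length(pmf) + length(p) - 1L, len))
      for (a in seq_along(pmf)) {
        jmax <- min(length(p), len - a + 1L)
        if (jmax < 1L) break
        out[a:(a + jmax - 1L)] <- out[a:(a + jmax - 1L)] + pmf[a] * p[seq_len(jmax)]
      }
      pmf <- out
    }
  }
  pmf
}

# Exhaustive isolation-window search: plain double loop over the same
# candidate grid used by score_windows().
oracle_best_window <- function(assignments, ions, feature_id, window_width,
                               center_grid_step, gamma = 1) {
  mz <- ions$mz[match(assignments$ion_id, ions$ion_id)]
  is_t <- !is.na(assignments$feature_id) & assignments$feature_id == feature_id
  tmz <- mz[is_t]
  gs <- center_grid_step
  centers <- seq(floor(min(tmz) / gs) * gs, ceiling(max(tmz) / gs) * gs, by = gs)
  best <- NULL
  for (ct in centers) {
    lo <- ct - window_width / 2
    hi <- ct + window_width / 2
    tc <- sum(tmz >= lo & tmz < hi)
    if (tc == 0) next
    oc <- sum(mz[!is_t] >= lo & mz[!is_t] < hi)
    purity <- tc / (tc + oc)
    score <- tc * purity^gamma
    cand <- list(center = ct, score = score, purity = purity, tc = tc, oc = oc)
    if (is.null(best) || score > best$score ||
        (score == best$score && (purity > best$purity ||
          (purity == best$purity && ct < best$center)))) {
      best <- cand
    }
  }
  best
}

# Brute-force masked-argmax peak picking on a density vector.
oracle_pick_apexes <- function(grid, density, threshold_frac, mask_halfwidth) {
  dens <- density
  stop_at <- threshold_frac * max(dens)
  apexes <- numeric()
  repeat {
    i <- which.max(dens)
    if (dens[i] < stop_at || dens[i] <= 0) break
    apexes <- c(apexes, grid[i])
    dens[abs(grid - grid[i]) <= mask_halfwidth] <- 0
  }
  apexes
}

# Linear-scan intact-mass-tag search.
oracle_imt_linear <- function(observed, candidates, tolerance_ppm) {
  rows <- list()
  for (k in seq_along(observed)) {
    for (j in seq_len(nrow(candidates))) {
      ppm <- 1e6 * (observed[k] - candidates$candidate_mass[j]) /
        candidates$candidate_mass[j]
      if (abs(ppm) <= tolerance_ppm) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = k, accession = candidates$accession[j],
          mod_set = candidates$mod_set[j],
          candidate_mass = candidates$candidate_mass[j], ppm_error = ppm)
      }
    }
  }
  do.call(rbind, rows)
}

# Gaussian tail-bound expectation for the fraction of ions whose
# round(slope/calib) equals the true charge, given the charge mix.
oracle_round_correct_rate <- function(charges, cv) {
  probs <- 2 * stats::pnorm(0.5 / (charges * cv)) - 1
  mean(probs)
}
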