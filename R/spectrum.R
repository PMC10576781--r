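# Mass-domain spectrum estimation and proteoform feature picking.

#' Kernel-density mass-domain spectrum
#'
#' Converts the neutral masses of charge-assigned ions into a continuous
#' mass-domain profile by Gaussian kernel density estimation on a uniform
#' grid. Every ion contributes unit area, so the integral of the density
#' equals the number of assigned ions.
#'
#' @param ions Ion tibble with a `neutral_mass` column (`NA` for unassigned
#'   ions, which are ignored).
#' @param bandwidth Gaussian kernel standard deviation in Da, or `"auto"` =
#'   `max(0.2, 5 ppm of the median mass)` (resolves the 1.00235 Da isotope
#'   spacing below roughly 30 kDa and merges it above).
#' @param grid_step Grid spacing in Da; default `bandwidth / 4`.
#' @return A `pims_spectrum`: list with `mass_grid`, `density`, `bandwidth`,
#'   `grid_step`, `n_ions`.
#' @export
build_mass_spectrum <- function(ions, bandwidth = "auto", grid_step = NULL) {
  masses <- ions$neutral_mass
  masses <- masses[is.finite(masses)]
  if (length(masses) == 0L) {
    rlang::abort("No charge-assigned ions: cannot build a mass spectrum.",
                 class = "pimsr_empty_spectrum")
  }
  if (identical(bandwidth, "auto")) {
    bandwidth <- max(0.2, 5e-6 * stats::median(masses))
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  if (is.null(grid_step)) grid_step <- bandwidth / 4
  stopifnot(grid_step > 0)

  pad <- 5 * bandwidth
  lo <- floor((min(masses) - pad) / grid_step) * grid_step
  hi <- max(masses) + pad
  grid <- seq(lo, hi, by = grid_step)
  counts <- tabulate(pmin(length(grid),
                          pmax(1L, round((masses - lo) / grid_step) + 1L)),
                     nbins = length(grid))
  half <- as.integer(ceiling(5 * bandwidth / grid_step))
  kernel <- stats::dnorm(seq(-half, half) * grid_step, sd = bandwidth)
  kernel <- kernel / (sum(kernel) * grid_step)  # exact unit area per ion
  # FFT convolution on a composite-friendly padded length (unpadded lengths
  # can make the mixed-radix FFT quadratic)
  full_len <- length(counts) + length(kernel) - 1L
  pad <- stats::nextn(full_len, c(2L, 3L, 5L))
  fc <- stats::fft(c(counts, numeric(pad - length(counts))))
  fk <- stats::fft(c(kernel, numeric(pad - length(kernel))))
  dens <- Re(stats::fft(fc * fk, inverse = TRUE)) / pad
  dens <- dens[(half + 1L):(half + length(grid))]
  dens[dens < 0] <- 0  # FFT rounding
  structure(
    list(mass_grid = grid, density = dens, bandwidth = bandwidth,
         grid_step = grid_step, n_ions = length(masses)),
    class = "pims_spectrum"
  )
}

#' @export
print.pims_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pims_spectrum> %d ions, %.0f-%.0f Da, bandwidth %.3g Da, step %.3g Da\n",
    x$n_ions, min(x$mass_grid), max(x$mass_grid), x$bandwidth, x$grid_step))
  invisible(x)
}

# Count ions with sorted masses within +/- ppm of each position.
.count_near <- function(sorted_masses, positions, ppm = 10) {
  tol <- positions * ppm * 1e-6
  hi <- findInterval(positions + tol, sorted_masses)
  lo <- findInterval(positions - tol, sorted_masses, left.open = TRUE) + 1L
  pmax(0L, hi - lo + 1L)
}

# Monoisotopic mass of a picked apex: align the observed per-isotope ion
# counts around the apex with the averagine pattern (cross-correlation over a
# few whole-isotope shifts) so an apex that differs from the theoretical
# most-abundant isotope by sampling does not shift the mono mass by a full
# isotope.
.mono_from_apex <- function(apex_mass, sorted_masses, ppm = 10,
                            max_shift = 2L) {
  pmf <- .averagine_pmf(apex_mass)
  k_apex <- which.max(pmf) - 1L
  shifts <- seq(-max_shift, max_shift)
  best <- c(score = -Inf, shift = 0)
  for (s in shifts) {
    mono <- apex_mass - (k_apex + s) * ISOTOPE_SPACING
    if (mono <= 0) next
    pos <- mono + (seq_along(pmf) - 1L) * ISOTOPE_SPACING
    obs <- .count_near(sorted_masses, pos, ppm)
    denom <- sqrt(sum(obs^2) * sum(pmf^2))
    sc <- if (denom > 0) sum(obs * pmf) / denom else -Inf
    if (sc > best["score"] ||
        (sc == best["score"] && abs(s) < abs(best["shift"]))) {
      best <- c(score = sc, shift = s)
    }
  }
  apex_mass - (k_apex + best[["shift"]]) * ISOTOPE_SPACING
}

#' Pick proteoform features from a mass spectrum
#'
#' Iterative peak picking: take the global density maximum, record a feature,
#' mask `+/- mask_halfwidth` around it, and repeat until the remaining
#' maximum falls below `rel_abundance_threshold` times the first maximum.
#' The apex is refined by parabolic interpolation, converted to a
#' monoisotopic mass using the averagine most-abundant-isotope offset (with a
#' cross-correlation phase check), and the feature's member ions are the ions
#' within +/- `match_ppm` of any of its 5--11 major isotope masses.
#'
#' @param spectrum A [build_mass_spectrum()] result.
#' @param ions The ion tibble the spectrum was built from (needs
#'   `neutral_mass` and `ion_id`).
#' @param rel_abundance_threshold Stop threshold as a fraction of the first
#'   (largest) density maximum.
#' @param mask_halfwidth Half-width of the mask in Da, or `"auto"` =
#'   `max(2.5, 2 x averagine envelope FWHM at the apex mass)`, which masks a
#'   whole isotope envelope.
#' @param match_ppm Ion-to-isotope matching tolerance in ppm.
#' @return A tibble of class `pims_features`: `feature_id`,
#'   `monoisotopic_mass`, `apex_mass`, `n_isotopes`, `isotope_masses`
#'   (list-column), `ion_count`, `member_ion_ids` (list-column),
#'   `relative_abundance` (fraction of the most ion-rich feature),
#'   `isotope_fit_score`. Features appear in pick (descending density) order.
#' @export
pick_features <- function(spectrum, ions, rel_abundance_threshold = 0.01,
                          mask_halfwidth = "auto", match_ppm = 10) {
  stopifnot(inherits(spectrum, "pims_spectrum"))
  if (!(rel_abundance_threshold > 0 && rel_abundance_threshold <= 1)) {
    rlang::abort("`rel_abundance_threshold` must be in (0, 1].",
                 class = "pimsr_invalid_input")
  }
  grid <- spectrum$mass_grid
  dens0 <- spectrum$density
  dens <- dens0
  step <- spectrum$grid_step
  auto_mask <- identical(mask_halfwidth, "auto")

  masses <- ions$neutral_mass
  keep <- is.finite(masses)
  ord <- order(masses[keep])
  sorted_masses <- masses[keep][ord]
  sorted_ids <- ions$ion_id[keep][ord]

  first_max <- max(dens)
  stop_at <- rel_abundance_threshold * first_max
  apexes <- numeric()
  repeat {
    i <- which.max(dens)
    if (dens[i] < stop_at || dens[i] <= 0) break
    # parabolic refinement of the apex on the un-masked density
    apex <- grid[i]
    if (i > 1L && i < length(grid)) {
      y1 <- dens0[i - 1L]; y2 <- dens0[i]; y3 <- dens0[i + 1L]
      den <- y1 - 2 * y2 + y3
      if (den < 0) apex <- grid[i] + 0.5 * step * (y1 - y3) / den
    }
    apexes <- c(apexes, apex)
    hw <- if (auto_mask) max(2.5, 2 * .envelope_fwhm(apex)) else mask_halfwidth
    dens[abs(grid - apex) <= hw] <- 0
  }

  feats <- purrr::map(seq_along(apexes), function(j) {
    apex <- apexes[j]
    mono <- .mono_from_apex(apex, sorted_masses, ppm = match_ppm)
    n_iso <- n_major_isotopes(mono)
    offs <- .major_isotope_offsets(mono, n_iso)
    iso_masses <- mono + offs * ISOTOPE_SPACING
    tol <- iso_masses * match_ppm * 1e-6
    hit_lo <- findInterval(iso_masses - tol, sorted_masses, left.open = TRUE) + 1L
    hit_hi <- findInterval(iso_masses + tol, sorted_masses)
    members <- unlist(purrr::map2(hit_lo, hit_hi, function(a, b) {
      if (b >= a) sorted_ids[a:b] else character()
    }))
    members <- unique(members)
    tibble::tibble(
      feature_id = sprintf("F%03d", j),
      monoisotopic_mass = mono,
      apex_mass = apex,
      n_isotopes = n_iso,
      isotope_masses = list(iso_masses),
      ion_count = length(members),
      member_ion_ids = list(members)
    )
  })
  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(feature_id = character(),
                          monoisotopic_mass = numeric(),
                          apex_mass = numeric(), n_isotopes = integer(),
                          isotope_masses = list(), ion_count = integer(),
                          member_ion_ids = list(),
                          relative_abundance = numeric(),
                          isotope_fit_score = numeric())
    class(out) <- c("pims_features", class(out))
    return(out)
  }
  out$relative_abundance <- out$ion_count / max(out$ion_count)
  out$isotope_fit_score <- vapply(seq_len(nrow(out)), function(j) {
    if (out$ion_count[j] == 0L) return(NA_real_)
    isotope_fit_score(out[j, ], ions)
  }, numeric(1))
  class(out) <- c("pims_features", class(out))
  out
}

#' Isotope-pattern fit score of a feature
#'
#' Cosine similarity between a feature's observed per-isotope member-ion
#' counts and the theoretical averagine intensities at its monoisotopic mass.
#' A simplified stand-in for full isotope-distribution fitting: 1 means the
#' observed envelope is exactly proportional to theory.
#'
#' @param feature One row of a [pick_features()] table.
#' @param ions Ion tibble with `neutral_mass`.
#' @param match_ppm Matching tolerance in ppm.
#' @return Cosine similarity in \[0, 1\].
#' @export
isotope_fit_score <- function(feature, ions, match_ppm = 10) {
  stopifnot(nrow(feature) == 1L)
  if (feature$ion_count[[1]] < 1L) {
    rlang::abort("Feature has no member ions; fit score undefined.",
                 class = "pimsr_invalid_input")
  }
  iso_masses <- feature$isotope_masses[[1]]
  mono <- feature$monoisotopic_mass[[1]]
  offs <- as.integer(round((iso_masses - mono) / ISOTOPE_SPACING))
  pmf <- .averagine_pmf(mono)
  theo <- pmf[offs + 1L]
  masses <- sort(ions$neutral_mass[is.finite(ions$neutral_mass)])
  obs <- .count_near(masses, iso_masses, ppm = match_ppm)
  denom <- sqrt(sum(obs^2) * sum(theo^2))
  if (denom == 0) return(0)
  sum(obs * theo) / denom
}
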