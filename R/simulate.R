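# Synthetic single-ion data generator.
#
# Emulates denaturing-electrospray individual-ion line scans: each proteoform
# carries an averagine isotope pattern, a Gaussian-like charge-state envelope
# and a spatial abundance profile along the line; uniform noise ions form the
# background. Every ion carries a ground-truth label so downstream stages can
# be scored.

#' Declare a proteoform for simulation
#'
#' @param id Label for the proteoform.
#' @param monoisotopic_mass Monoisotopic mass in Da (> 0).
#' @param total_ion_budget Expected total number of ions emitted over the
#'   whole experiment (Poisson mean, >= 0).
#' @param charge_mu Mean of the charge-state envelope.
#' @param charge_sigma Standard deviation of the charge-state envelope.
#' @param spatial_profile Non-negative weight per scan index along one line
#'   (any length; it is interpolated to the geometry's `scans_per_line`).
#'   Scalar 1 gives a flat profile.
#' @param class_effect Optional named numeric of multiplicative abundance
#'   factors per sample class, for two-class simulations.
#' @return One-row tibble; rows from repeated calls can be bound together
#'   into a spec table for [simulate_line_scan()].
#' @export
proteoform_spec <- function(id, monoisotopic_mass, total_ion_budget,
                            charge_mu, charge_sigma = 1.5,
                            spatial_profile = 1, class_effect = NULL) {
  if (!is.finite(monoisotopic_mass) || monoisotopic_mass <= 0) {
    rlang::abort("`monoisotopic_mass` must be positive.",
                 class = "pimsr_invalid_input")
  }
  if (!is.finite(total_ion_budget) || total_ion_budget < 0) {
    rlang::abort("`total_ion_budget` must be >= 0.",
                 class = "pimsr_invalid_input")
  }
  if (any(spatial_profile < 0) || !any(spatial_profile > 0)) {
    rlang::abort("`spatial_profile` must be non-negative with positive sum.",
                 class = "pimsr_invalid_input")
  }
  tibble::tibble(
    id = as.character(id),
    monoisotopic_mass = monoisotopic_mass,
    total_ion_budget = total_ion_budget,
    charge_mu = charge_mu,
    charge_sigma = charge_sigma,
    spatial_profile = list(as.numeric(spatial_profile)),
    class_effect = list(class_effect)
  )
}

# Gaussian bump spatial profile helper used throughout the tests/examples.
#' Gaussian spatial abundance profile
#'
#' Convenience constructor for a smooth single-maximum spatial profile over
#' `n_scans` scan positions.
#'
#' @param n_scans Number of scan positions.
#' @param center Center, as a fraction of the line (0..1).
#' @param width Standard deviation, as a fraction of the line.
#' @param floor Baseline added everywhere (relative to peak height 1).
#' @return Numeric vector of length `n_scans`.
#' @export
gaussian_profile <- function(n_scans, center = 0.5, width = 0.1, floor = 0.02) {
  x <- (seq_len(n_scans) - 0.5) / n_scans
  exp(-0.5 * ((x - center) / width)^2) + floor
}

#' Simulate a single-ion line-scan dataset
#'
#' For every proteoform the per-scan ion count is Poisson with mean
#' proportional to its spatial profile (scaled so the expected total over all
#' lines equals `total_ion_budget`). Each ion draws an integer charge from
#' the rounded Gaussian charge envelope (clamped to >= 1) and an isotopologue
#' from the averagine pattern; its m/z is `(mass + z * M_PROTON) / z` and its
#' STORI slope is `calib_slope * z * (1 + N(0, slope_noise_cv))`. Noise ions
#' arrive uniformly over scans and m/z.
#'
#' @param specs Spec table from [proteoform_spec()] rows.
#' @param geometry A [scan_geometry()].
#' @param calib_slope Charge-calibration slope (slope units per charge).
#' @param noise_ion_rate Expected noise ions per scan.
#' @param slope_noise_cv Coefficient of variation of the STORI slope noise.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param noise_mz_range m/z range of the uniform noise background.
#' @param noise_slope_range Charge-equivalent slope range of noise ions
#'   (multiplied by `calib_slope`).
#' @return A `pims_dataset`: list with tibbles `ions` (ion_id, mz,
#'   stori_slope, scan_index, line_index), `truth` (ion_id, source,
#'   true_charge, true_isotope, true_mass) and the `geometry`.
#' @export
simulate_line_scan <- function(specs, geometry, calib_slope,
                               noise_ion_rate = 0, slope_noise_cv = 0.02,
                               seed = 1L, noise_mz_range = c(400, 2500),
                               noise_slope_range = c(1, 60)) {
  stopifnot(inherits(geometry, "pims_geometry"))
  if (!is.finite(calib_slope) || calib_slope <= 0) {
    rlang::abort("`calib_slope` must be positive.",
                 class = "pimsr_invalid_input")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  nspl <- geometry$scans_per_line
  nl <- geometry$n_lines
  rows <- list()
  truths <- list()
  if (!is.null(specs) && nrow(specs) > 0) {
    for (si in seq_len(nrow(specs))) {
      sp <- specs[si, ]
      prof <- sp$spatial_profile[[1]]
      if (length(prof) == 1L) prof <- rep(prof, nspl)
      if (length(prof) != nspl) {
        prof <- stats::approx(seq(0, 1, length.out = length(prof)), prof,
                              xout = seq(0, 1, length.out = nspl))$y
      }
      lam <- sp$total_ion_budget * prof / sum(prof) / nl
      pmf <- .averagine_pmf(sp$monoisotopic_mass)
      for (li in seq_len(nl) - 1L) {
        counts <- stats::rpois(nspl, lam)
        n <- sum(counts)
        if (n == 0L) next
        scan <- rep(seq_len(nspl) - 1L, counts)
        z <- pmax(1L, as.integer(round(stats::rnorm(n, sp$charge_mu,
                                                    sp$charge_sigma))))
        k <- sample.int(length(pmf), n, replace = TRUE, prob = pmf) - 1L
        mass <- sp$monoisotopic_mass + k * ISOTOPE_SPACING
        mz <- (mass + z * M_PROTON) / z
        slope <- calib_slope * z * (1 + stats::rnorm(n, 0, slope_noise_cv))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mz = mz, stori_slope = slope, scan_index = scan, line_index = li
        )
        truths[[length(truths) + 1L]] <- tibble::tibble(
          source = sp$id, true_charge = z, true_isotope = k, true_mass = mass
        )
      }
    }
  }
  if (noise_ion_rate > 0) {
    for (li in seq_len(nl) - 1L) {
      counts <- stats::rpois(nspl, noise_ion_rate)
      n <- sum(counts)
      if (n == 0L) next
      scan <- rep(seq_len(nspl) - 1L, counts)
      mz <- stats::runif(n, noise_mz_range[1], noise_mz_range[2])
      slope <- calib_slope * stats::runif(n, noise_slope_range[1],
                                          noise_slope_range[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        mz = mz, stori_slope = slope, scan_index = scan, line_index = li
      )
      truths[[length(truths) + 1L]] <- tibble::tibble(
        source = rep("noise", n), true_charge = NA_integer_,
        true_isotope = NA_integer_, true_mass = NA_real_
      )
    }
  }
  ions <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  if (nrow(ions) == 0L) {
    ions <- tibble::tibble(mz = numeric(), stori_slope = numeric(),
                           scan_index = integer(), line_index = integer())
    truth <- tibble::tibble(source = character(), true_charge = integer(),
                            true_isotope = integer(), true_mass = numeric())
  }
  ord <- order(ions$line_index, ions$scan_index, ions$mz)
  ions <- ions[ord, ]
  truth <- truth[ord, ]
  ids <- sprintf("ion%06d", seq_len(nrow(ions)))
  ions <- tibble::tibble(ion_id = ids, ions)
  truth <- tibble::tibble(ion_id = ids, truth)
  structure(list(ions = ions, truth = truth, geometry = geometry),
            class = "pims_dataset")
}

#' @export
print.pims_dataset <- function(x, ...) {
  cat(sprintf("<pims_dataset> %d ions (%d noise), %d line(s) x %d scans\n",
              nrow(x$ions), sum(x$truth$source == "noise"),
              x$geometry$n_lines, x$geometry$scans_per_line))
  invisible(x)
}

# save/restore the global RNG state so seeded simulators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a two-class region count table
#'
#' Draws a regions x proteoforms ion-count matrix for a two-class
#' region-of-interest experiment. Baseline per-region means are log-normal
#' across proteoforms; a fixed fraction of proteoforms is truly differential
#' with class means separated by `effect_log2fc` (direction random per
#' proteoform, the effect split symmetrically between the classes). Counts
#' are negative-binomial with the given dispersion (Poisson as
#' `dispersion` tends to 0).
#'
#' @param n_proteoforms Number of simulated proteoforms.
#' @param n_regions_per_class Regions per class; either a single number or a
#'   length-2 vector (class A, class B).
#' @param frac_differential Fraction of proteoforms that are truly
#'   differential (0..1).
#' @param effect_log2fc Absolute log2 fold change of differential
#'   proteoforms.
#' @param dispersion Negative-binomial dispersion (variance = mu + mu^2 *
#'   dispersion); <= 0 gives Poisson counts.
#' @param seed Integer seed.
#' @param classes Character vector of the two class labels.
#' @param mean_log Mean of log(baseline mean count) across proteoforms.
#' @param sd_log Standard deviation of log(baseline mean count).
#' @return List with `regions` (wide tibble: region_id, class_label,
#'   total_ions, one count column per proteoform; feature columns are
#'   recorded in the `feature_cols` attribute) and `truth` (feature_id,
#'   differential flag, true_log2fc signed as class A over class B).
#' @export
simulate_two_class_regions <- function(n_proteoforms, n_regions_per_class,
                                       frac_differential = 0.3,
                                       effect_log2fc = 1.0,
                                       dispersion = 0.1, seed = 1L,
                                       classes = c("stroma", "tumor"),
                                       mean_log = log(5), sd_log = 1) {
  if (frac_differential < 0 || frac_differential > 1) {
    rlang::abort("`frac_differential` must be in [0, 1].",
                 class = "pimsr_invalid_input")
  }
  stopifnot(length(classes) == 2L)
  if (length(n_regions_per_class) == 1L) {
    n_regions_per_class <- rep(n_regions_per_class, 2L)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  p <- as.integer(n_proteoforms)
  base_mu <- exp(stats::rnorm(p, mean_log, sd_log))
  n_diff <- round(frac_differential * p)
  diff_idx <- if (n_diff > 0) sample.int(p, n_diff) else integer()
  sign_fc <- numeric(p)
  if (n_diff > 0) sign_fc[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE)
  true_lfc <- sign_fc * effect_log2fc
  mu_a <- base_mu * 2^(true_lfc / 2)
  mu_b <- base_mu * 2^(-true_lfc / 2)

  draw <- function(n, mu) {
    m <- matrix(0L, nrow = n, ncol = p)
    for (j in seq_len(p)) {
      m[, j] <- if (dispersion > 1e-12) {
        stats::rnbinom(n, size = 1 / dispersion, mu = mu[j])
      } else {
        stats::rpois(n, mu[j])
      }
    }
    m
  }
  xa <- draw(n_regions_per_class[1], mu_a)
  xb <- draw(n_regions_per_class[2], mu_b)
  x <- rbind(xa, xb)
  feat <- sprintf("P%04d", seq_len(p))
  colnames(x) <- feat
  regions <- tibble::tibble(
    region_id = sprintf("R%04d", seq_len(nrow(x))),
    class_label = rep(classes, n_regions_per_class),
    total_ions = rowSums(x)
  )
  regions <- dplyr::bind_cols(regions, tibble::as_tibble(x))
  attr(regions, "feature_cols") <- feat
  truth <- tibble::tibble(
    feature_id = feat,
    differential = seq_len(p) %in% diff_idx,
    true_log2fc = true_lfc
  )
  list(regions = regions, truth = truth)
}
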