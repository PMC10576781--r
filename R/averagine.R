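# Averagine isotope distribution model.
#
# Proteins of unknown sequence are modelled with the standard "averagine"
# average amino-acid composition; the aggregated isotope distribution is the
# convolution of the per-element neutron-offset distributions.

# Convolution power with truncation: distribution of the summed neutron
# offset of `n` i.i.d. atoms, each with single-atom pmf `p`, truncated to
# `len` terms (offsets 0..len-1). Exponentiation by squaring keeps this
# O(log n) short convolutions.
.conv_pow <- function(p, n, len) {
  trim <- function(x) {
    x <- x[seq_len(min(length(x), len))]
    x
  }
  conv <- function(a, b) {
    out <- numeric(min(length(a) + length(b) - 1L, len))
    for (i in seq_along(a)) {
      jmax <- min(length(b), len - i + 1L)
      if (jmax < 1L) break
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
    out
  }
  result <- 1
  base <- trim(p)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- conv(result, base)
    n <- n %/% 2L
    if (n > 0L) base <- conv(base, base)
  }
  if (length(result) < len) result <- c(result, numeric(len - length(result)))
  result
}

#' Averagine elemental composition at a target mass
#'
#' Scales the averagine monomer (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per
#' 111.1254 Da) to `monoisotopic_mass`, rounds C/N/O/S to integer atom counts
#' and adjusts the hydrogen count so the monoisotopic mass of the composition
#' matches the target as closely as possible.
#'
#' @param monoisotopic_mass Target monoisotopic mass in Da (> 0).
#' @return Named integer vector of atom counts for C, H, N, O, S.
#' @export
averagine_composition <- function(monoisotopic_mass) {
  stopifnot(is.numeric(monoisotopic_mass), length(monoisotopic_mass) == 1L)
  if (!is.finite(monoisotopic_mass) || monoisotopic_mass <= 0) {
    rlang::abort("`monoisotopic_mass` must be a positive finite number.",
                 class = "pimsr_invalid_input")
  }
  units <- monoisotopic_mass / .averagine_unit_mass
  counts <- round(.averagine_unit[c("C", "N", "O", "S")] * units)
  mono <- vapply(.element_data, `[[`, numeric(1), "mono")
  rest <- sum(counts * mono[names(counts)])
  n_h <- max(0, round((monoisotopic_mass - rest) / mono[["H"]]))
  out <- c(C = counts[["C"]], H = n_h, N = counts[["N"]],
           O = counts[["O"]], S = counts[["S"]])
  storage.mode(out) <- "integer"
  out
}

# Full aggregated isotope pmf (by neutron offset) of the averagine
# composition at `monoisotopic_mass`, truncated to `len` offsets. When `len`
# is NULL a length covering essentially all probability mass is chosen from
# the mean and variance of the offset distribution.
.averagine_pmf <- function(monoisotopic_mass, len = NULL) {
  comp <- averagine_composition(monoisotopic_mass)
  if (is.null(len)) {
    mu <- 7.2e-4 * monoisotopic_mass
    len <- max(8L, as.integer(ceiling(mu + 8 * sqrt(mu + 1) + 4)))
  }
  pmf <- 1
  for (el in names(comp)) {
    if (comp[[el]] > 0L) {
      p_el <- .conv_pow(.element_data[[el]]$ab, comp[[el]], len)
      pmf <- .conv_pow_pair(pmf, p_el, len)
    }
  }
  if (length(pmf) < len) pmf <- c(pmf, numeric(len - length(pmf)))
  pmf
}

# single convolution of two truncated pmfs
.conv_pow_pair <- function(a, b, len) {
  out <- numeric(min(length(a) + length(b) - 1L, len))
  for (i in seq_along(a)) {
    jmax <- min(length(b), len - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Theoretical isotope pattern at a given mass
#'
#' Computes the first `n_isotopes` isotopologue centroids of an averagine
#' protein with the given monoisotopic mass. Centroids are spaced by the
#' fixed [ISOTOPE_SPACING]; intensities are the aggregated isotope
#' probabilities normalised so the most intense returned isotope is 1.
#'
#' @param monoisotopic_mass Monoisotopic mass in Da (> 0).
#' @param n_isotopes Number of isotopologues to return (1--30).
#' @return A tibble with columns `isotope` (offset 0, 1, ...), `isotope_mass`
#'   (Da) and `rel_intensity` (max = 1).
#' @examples
#' averagine_isotopes(10000, 11)
#' @export
averagine_isotopes <- function(monoisotopic_mass, n_isotopes = 10L) {
  if (!is.numeric(n_isotopes) || length(n_isotopes) != 1L ||
      n_isotopes < 1 || n_isotopes > 30) {
    rlang::abort("`n_isotopes` must be a single integer in 1..30.",
                 class = "pimsr_invalid_input")
  }
  n_isotopes <- as.integer(n_isotopes)
  pmf <- .averagine_pmf(monoisotopic_mass, len = max(n_isotopes, 8L))
  intens <- pmf[seq_len(n_isotopes)]
  intens <- intens / max(intens)
  tibble::tibble(
    isotope = seq_len(n_isotopes) - 1L,
    isotope_mass = monoisotopic_mass + (seq_len(n_isotopes) - 1L) * ISOTOPE_SPACING,
    rel_intensity = intens
  )
}

#' Number of major isotopes used for a proteoform
#'
#' Matching of ions to a proteoform uses its 5--11 most intense isotopes
#' depending on mass: 5 below 10 kDa, scaling linearly to 11 at and above
#' 40 kDa.
#'
#' @param mass Proteoform mass in Da.
#' @return Integer count in 5..11.
#' @export
n_major_isotopes <- function(mass) {
  n <- round(5 + 6 * (mass - 10000) / 30000)
  as.integer(pmin(11, pmax(5, n)))
}

# FWHM (Da) of the averagine isotope envelope at a given mass, computed from
# the aggregated pmf (number of isotopes at or above half the apex times the
# isotope spacing).
.envelope_fwhm <- function(mass) {
  pmf <- .averagine_pmf(mass)
  max(1, sum(pmf >= max(pmf) / 2)) * ISOTOPE_SPACING
}

# Indices (neutron offsets, 0-based) of the `n` most intense isotopes of the
# averagine pattern at `mass`; contiguous by unimodality of the pattern.
.major_isotope_offsets <- function(mass, n) {
  pmf <- .averagine_pmf(mass)
  n <- min(n, length(pmf))
  ord <- order(pmf, decreasing = TRUE)[seq_len(n)]
  sort(ord - 1L)
}
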