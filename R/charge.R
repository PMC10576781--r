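# Charge assignment from STORI slopes.

#' Neutral mass from m/z and charge
#'
#' `mass = mz * z - z * M_PROTON`; the inverse of [mz_from_mass()].
#'
#' @param mz m/z in Th.
#' @param z Integer charge (>= 1).
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass(1000, 10)  # 9989.92723534
#' @export
neutral_mass <- function(mz, z) {
  mz * z - z * M_PROTON
}

#' m/z of a neutral mass at a given charge
#'
#' @param mass Neutral mass in Da.
#' @param z Integer charge (>= 1).
#' @return m/z in Th.
#' @export
mz_from_mass <- function(mass, z) {
  (mass + z * M_PROTON) / z
}

#' Assign integer charges to ions by slope voting
#'
#' Each ion's STORI slope is compared to the instrument charge-calibration
#' slope. Because a single slope estimate is noisy, `n_votes` resampled slope
#' estimates are drawn around the observed slope (perturbed by its estimated
#' relative uncertainty) and each votes for `round(slope / calib_slope)`
#' clamped to >= 1. The charge is assigned only when the modal vote reaches
#' `vote_agreement` of the votes; otherwise the ion is left unassigned.
#' Assigned ions get their neutral mass via [neutral_mass()].
#'
#' @param ions Ion tibble with columns `mz` and `stori_slope`.
#' @param calib_slope Calibration slope in slope units per charge (> 0).
#' @param n_votes Number of resampled votes per ion.
#' @param vote_agreement Minimum modal vote share for assignment.
#' @param slope_cv Relative slope uncertainty used for the resampling; `NULL`
#'   estimates it robustly from the deviations of `slope/calib_slope` from
#'   the nearest integer.
#' @return The ion tibble with columns `charge` (integer, `NA` when
#'   unassigned), `neutral_mass` and `vote_share` added. Uses the R random
#'   stream; seed it for reproducibility.
#' @export
assign_charge <- function(ions, calib_slope, n_votes = 25L,
                          vote_agreement = 0.8, slope_cv = NULL) {
  if (!is.finite(calib_slope) || calib_slope <= 0) {
    rlang::abort("`calib_slope` must be positive.",
                 class = "pimsr_invalid_input")
  }
  stopifnot(n_votes >= 1)
  x <- ions$stori_slope / calib_slope
  n <- length(x)
  if (n == 0L) {
    return(dplyr::mutate(ions, charge = integer(), neutral_mass = numeric(),
                         vote_share = numeric()))
  }
  if (is.null(slope_cv)) {
    z0 <- pmax(1, round(x))
    slope_cv <- max(1e-4, stats::mad((x - round(x)) / z0))
  }
  votes <- matrix(x, n, n_votes) *
    (1 + matrix(stats::rnorm(n * n_votes, 0, slope_cv), n, n_votes))
  votes <- round(votes)
  votes[votes < 1] <- 1
  modal <- apply(votes, 1L, function(v) {
    tb <- tabulate(v)
    best <- which.max(tb)
    c(best, tb[best])
  })
  charge <- as.integer(modal[1L, ])
  share <- modal[2L, ] / n_votes
  ok <- share >= vote_agreement
  charge[!ok] <- NA_integer_
  dplyr::mutate(ions,
                charge = charge,
                neutral_mass = neutral_mass(.data$mz, charge),
                vote_share = share)
}
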