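# Intact-mass-tag annotation against a protein database.

#' Default modification deltas for candidate expansion
#'
#' Initiator-methionine loss, water loss, monoacetylation and
#' monophosphorylation (monoisotopic Da).
#'
#' @return Named numeric vector of mass deltas.
#' @export
imt_default_mods <- function() {
  c(met_loss = -131.040485, water_loss = -18.010565,
    acetyl = 42.010565, phospho = 79.966331)
}

#' Expand a protein database into modified mass candidates
#'
#' Per protein: the unmodified mass, each single modification, and every
#' unordered pair of distinct modifications (one-to-one combinations) — 11
#' candidates per protein with the default four modifications.
#'
#' @param db Tibble with columns `accession` and `base_mass` (monoisotopic
#'   Da, > 0); extra columns are carried along.
#' @param mods Named numeric vector of modification deltas.
#' @return Tibble `accession`, `base_mass`, `mod_set` (`""`, `"acetyl"`,
#'   `"acetyl+phospho"`, ...), `candidate_mass`, sorted by candidate mass.
#' @export
imt_candidates <- function(db, mods = imt_default_mods()) {
  stopifnot(all(c("accession", "base_mass") %in% names(db)))
  if (any(db$base_mass <= 0)) {
    rlang::abort("All `base_mass` values must be positive.",
                 class = "pimsr_invalid_input")
  }
  nm <- names(mods)
  sets <- c(list(character(0)), as.list(nm),
            utils::combn(nm, 2L, simplify = FALSE))
  deltas <- vapply(sets, function(s) sum(mods[s]), numeric(1))
  labels <- vapply(sets, paste, character(1), collapse = "+")
  out <- tidyr::expand_grid(
    db[, c("accession", "base_mass")],
    tibble::tibble(mod_set = labels, delta = deltas)
  )
  out$candidate_mass <- out$base_mass + out$delta
  out$delta <- NULL
  out[order(out$candidate_mass), ]
}

#' Recalibrate observed masses against anchor identifications
#'
#' Fits a linear ppm-drift model (`ppm error ~ mass`) on anchor pairs of
#' (observed, true) masses by least squares and applies the correction to all
#' observed masses. Anchor residuals are reported so lack of fit (e.g. a
#' nonlinear drift) is visible rather than hidden.
#'
#' @param observed_masses Numeric vector of observed masses (Da).
#' @param anchors Tibble/data frame with columns `observed` and `true` (>= 2
#'   rows).
#' @return Corrected masses, with attributes `coefficients` (intercept ppm,
#'   ppm per Da) and `anchor_residuals_ppm`.
#' @export
recalibrate_masses <- function(observed_masses, anchors) {
  stopifnot(all(c("observed", "true") %in% names(anchors)))
  if (nrow(anchors) < 2L) {
    rlang::abort("Need at least two calibration anchors.",
                 class = "pimsr_insufficient_anchors")
  }
  ppm <- 1e6 * (anchors$observed - anchors$true) / anchors$true
  fit <- stats::lm(ppm ~ mass, data = data.frame(ppm = ppm,
                                                 mass = anchors$true))
  drift <- stats::predict(fit, newdata = data.frame(mass = observed_masses))
  corrected <- observed_masses / (1 + drift * 1e-6)
  attr(corrected, "coefficients") <- stats::coef(fit)
  attr(corrected, "anchor_residuals_ppm") <- unname(stats::residuals(fit))
  corrected
}

#' Intact-mass-tag search
#'
#' Matches observed proteoform masses against a candidate table within a ppm
#' tolerance. The candidate index is searched by bisection; results are
#' identical to a linear scan.
#'
#' @param observed Numeric vector of observed masses (optionally named by
#'   feature id).
#' @param candidates An [imt_candidates()] table.
#' @param tolerance_ppm Match tolerance in ppm (the stringent intact-mass
#'   convention is 1.5 ppm).
#' @return Tibble `feature_id` (names of `observed`, or `obs<k>`),
#'   `observed_mass`, `accession`, `mod_set`, `candidate_mass`, `ppm_error`
#'   (`1e6 * (observed - candidate) / candidate`), sorted per query by
#'   absolute ppm error.
#' @export
imt_match <- function(observed, candidates, tolerance_ppm = 1.5) {
  stopifnot(tolerance_ppm > 0)
  cand <- candidates[order(candidates$candidate_mass), ]
  cm <- cand$candidate_mass
  ids <- names(observed)
  if (is.null(ids)) ids <- sprintf("obs%d", seq_along(observed))
  rows <- purrr::map(seq_along(observed), function(k) {
    obs <- observed[[k]]
    # |1e6 (obs - c)/c| <= tol  <=>  obs/(1+tol*1e-6) <= c <= obs/(1-tol*1e-6)
    lo <- obs / (1 + tolerance_ppm * 1e-6)
    hi <- obs / (1 - tolerance_ppm * 1e-6)
    i1 <- findInterval(lo, cm, left.open = TRUE) + 1L
    i2 <- findInterval(hi, cm)
    if (i2 < i1) return(NULL)
    hit <- cand[i1:i2, ]
    ppm <- 1e6 * (obs - hit$candidate_mass) / hit$candidate_mass
    out <- tibble::tibble(feature_id = ids[k], observed_mass = obs,
                          accession = hit$accession, mod_set = hit$mod_set,
                          candidate_mass = hit$candidate_mass,
                          ppm_error = ppm)
    out[order(abs(out$ppm_error), out$accession, out$mod_set), ]
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(feature_id = character(), observed_mass = numeric(),
                          accession = character(), mod_set = character(),
                          candidate_mass = numeric(), ppm_error = numeric())
  }
  out
}
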