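# Precursor assignment and isolation-window selection.

#' Assign ions to precursor features
#'
#' Every charge-assigned ion is assigned to the feature whose nearest major
#' isotope mass is closest to the ion's neutral mass, provided the distance
#' is at most `inclusion_halfwidth`; otherwise the ion stays unassigned.
#' Ties between features are broken toward the lower feature mass.
#'
#' @param ions Ion tibble with `ion_id` and `neutral_mass`.
#' @param features A [pick_features()] table (non-empty).
#' @param inclusion_halfwidth Inclusion half-window in Da around each isotope
#'   mass (the user-set n of "within +/- n Da").
#' @return Assignment tibble `ion_id`, `feature_id` (`NA` when unassigned),
#'   `mass_delta`; the half-width is kept in the `inclusion_halfwidth`
#'   attribute.
#' @export
assign_ions <- function(ions, features, inclusion_halfwidth = 2) {
  if (is.null(features) || nrow(features) == 0L) {
    rlang::abort("`features` must be non-empty.", class = "pimsr_invalid_input")
  }
  if (!"neutral_mass" %in% names(ions)) {
    rlang::abort("`ions` has no `neutral_mass` column; run assign_charge() first.",
                 class = "pimsr_invalid_input")
  }
  stopifnot(inclusion_halfwidth > 0)
  pos <- tibble::tibble(
    iso_mass = unlist(features$isotope_masses),
    feature_id = rep(features$feature_id,
                     lengths(features$isotope_masses)),
    feature_mass = rep(features$monoisotopic_mass,
                       lengths(features$isotope_masses))
  )
  pos <- pos[order(pos$iso_mass, pos$feature_mass), ]

  m <- ions$neutral_mass
  n <- length(m)
  feature_id <- rep(NA_character_, n)
  delta <- rep(NA_real_, n)
  ok <- which(is.finite(m))
  if (length(ok)) {
    idx <- findInterval(m[ok], pos$iso_mass)
    lo <- pmax(1L, idx)
    hi <- pmin(nrow(pos), idx + 1L)
    d_lo <- abs(m[ok] - pos$iso_mass[lo])
    d_hi <- abs(m[ok] - pos$iso_mass[hi])
    # prefer smaller distance; on exact ties, the lower feature mass
    pick_hi <- d_hi < d_lo |
      (d_hi == d_lo & pos$feature_mass[hi] < pos$feature_mass[lo])
    best <- ifelse(pick_hi, hi, lo)
    best_d <- pmin(d_lo, d_hi)
    inside <- best_d <= inclusion_halfwidth
    feature_id[ok[inside]] <- pos$feature_id[best[inside]]
    delta[ok[inside]] <- (m[ok] - pos$iso_mass[best])[inside]
  }
  out <- tibble::tibble(ion_id = ions$ion_id, feature_id = feature_id,
                        mass_delta = delta)
  attr(out, "inclusion_halfwidth") <- inclusion_halfwidth
  out
}

#' In-silico purified m/z profile of one precursor
#'
#' Histogram over m/z of only the ions assigned to `feature_id` (or of the
#' unassigned ions when `feature_id` is `NA`). Bins are anchored at integer
#' multiples of `mz_bin` so profiles of different features partition the
#' full-ion histogram.
#'
#' @param assignments An [assign_ions()] table.
#' @param ions Matching ion tibble (with `mz`).
#' @param feature_id Feature label, or `NA` for the unassigned pool.
#' @param mz_bin Bin width in Th.
#' @return Tibble `mz_low`, `mz_center`, `count` for non-empty bins.
#' @export
reconstruct_mz_profile <- function(assignments, ions, feature_id,
                                   mz_bin = 1) {
  stopifnot(mz_bin > 0)
  if (!is.na(feature_id) && !feature_id %in% assignments$feature_id) {
    rlang::abort(sprintf("Unknown feature_id '%s'.", feature_id),
                 class = "pimsr_lookup_error")
  }
  sel <- if (is.na(feature_id)) {
    is.na(assignments$feature_id)
  } else {
    !is.na(assignments$feature_id) & assignments$feature_id == feature_id
  }
  mz <- ions$mz[match(assignments$ion_id[sel], ions$ion_id)]
  bin <- floor(mz / mz_bin)
  tb <- table(bin)
  tibble::tibble(
    mz_low = as.numeric(names(tb)) * mz_bin,
    mz_center = (as.numeric(names(tb)) + 0.5) * mz_bin,
    count = as.integer(tb)
  )
}

#' Score candidate isolation windows for one target
#'
#' Enumerates candidate window centers on a grid over the target's occupied
#' m/z range and scores each window `[center - width/2, center + width/2)` by
#' `target_ion_count * purity^gamma`, where purity is the fraction of ions in
#' the window belonging to the target. Windows are returned sorted by score
#' (ties: higher purity, then lower center m/z) and annotated with the
#' co-isolating features they contain.
#'
#' @param assignments An [assign_ions()] table.
#' @param ions Matching ion tibble.
#' @param feature_id Target feature label.
#' @param window_width Isolation width in Th (> 0).
#' @param center_grid_step Candidate-center spacing; default `width / 8`.
#' @param gamma Purity exponent in the score.
#' @param annotate_top Number of top windows to annotate with their
#'   co-isolating feature list (annotation is the expensive part; `Inf`
#'   annotates all).
#' @return Tibble `center_mz`, `width`, `target_ion_count`,
#'   `other_ion_count`, `purity`, `score`, `coisolating` (list-column of
#'   tibbles `feature_id`, `ion_count`, sorted by count). Empty when the
#'   target has no ions.
#' @export
score_windows <- function(assignments, ions, feature_id, window_width = 4,
                          center_grid_step = NULL, gamma = 1,
                          annotate_top = 25L) {
  stopifnot(window_width > 0)
  if (is.null(center_grid_step)) center_grid_step <- window_width / 8
  stopifnot(center_grid_step > 0)
  empty <- tibble::tibble(center_mz = numeric(), width = numeric(),
                          target_ion_count = integer(),
                          other_ion_count = integer(), purity = numeric(),
                          score = numeric(), coisolating = list())
  is_target <- !is.na(assignments$feature_id) &
    assignments$feature_id == feature_id
  mz_all <- ions$mz[match(assignments$ion_id, ions$ion_id)]
  tmz <- sort(mz_all[is_target])
  if (length(tmz) == 0L) return(empty)
  omz <- sort(mz_all[!is_target])

  gs <- center_grid_step
  centers <- seq(floor(min(tmz) / gs) * gs, ceiling(max(tmz) / gs) * gs,
                 by = gs)
  lo <- centers - window_width / 2
  hi <- centers + window_width / 2
  cnt_in <- function(sorted, lo, hi) {
    findInterval(hi, sorted, left.open = TRUE) -
      findInterval(lo, sorted, left.open = TRUE)
  }
  tc <- cnt_in(tmz, lo, hi)
  oc <- cnt_in(omz, lo, hi)
  keep <- tc > 0L
  if (!any(keep)) return(empty)
  centers <- centers[keep]; tc <- tc[keep]; oc <- oc[keep]
  purity <- tc / (tc + oc)
  score <- tc * purity^gamma
  ord <- order(-score, -purity, centers)
  out <- tibble::tibble(
    center_mz = centers[ord], width = window_width,
    target_ion_count = as.integer(tc[ord]),
    other_ion_count = as.integer(oc[ord]),
    purity = purity[ord], score = score[ord]
  )
  n_ann <- min(nrow(out), annotate_top)
  ann <- vector("list", nrow(out))
  if (n_ann > 0) {
    other_feat <- assignments$feature_id
    for (j in seq_len(n_ann)) {
      inside <- mz_all >= out$center_mz[j] - window_width / 2 &
        mz_all < out$center_mz[j] + window_width / 2 & !is_target &
        !is.na(other_feat)
      if (any(inside)) {
        co <- dplyr::count(tibble::tibble(feature_id = other_feat[inside]),
                           .data$feature_id, name = "ion_count")
        ann[[j]] <- dplyr::arrange(co, dplyr::desc(.data$ion_count),
                                   .data$feature_id)
      } else {
        ann[[j]] <- tibble::tibble(feature_id = character(),
                                   ion_count = integer())
      }
    }
  }
  out$coisolating <- ann
  out
}

#' Select fragmentation targets and their best isolation windows
#'
#' Filters the feature list by mass range and relative abundance, scores
#' isolation windows for each remaining feature, and attaches the best
#' window when its purity reaches `min_purity` (the feature is reported
#' windowless otherwise).
#'
#' @param features A [pick_features()] table.
#' @param assignments An [assign_ions()] table.
#' @param ions Matching ion tibble.
#' @param mass_range Length-2 numeric mass filter in Da.
#' @param rel_abundance_threshold Minimum relative abundance of a feature.
#' @param window_width,gamma,center_grid_step Passed to [score_windows()].
#' @param min_purity Minimum purity for a window to be accepted.
#' @return Tibble ordered by feature mass: feature columns plus `has_window`,
#'   `center_mz`, `width`, `target_ion_count`, `other_ion_count`, `purity`,
#'   `score`, `coisolating`.
#' @export
select_targets <- function(features, assignments, ions,
                           mass_range = c(0, Inf),
                           rel_abundance_threshold = 0.01,
                           window_width = 4, min_purity = 0.8, gamma = 1,
                           center_grid_step = NULL) {
  stopifnot(length(mass_range) == 2L, mass_range[1] <= mass_range[2])
  sel <- features$monoisotopic_mass >= mass_range[1] &
    features$monoisotopic_mass <= mass_range[2] &
    features$relative_abundance >= rel_abundance_threshold
  feats <- features[sel, ]
  feats <- feats[order(feats$monoisotopic_mass), ]
  win_cols <- tibble::tibble(
    has_window = logical(0), center_mz = numeric(0), width = numeric(0),
    target_ion_count = integer(0), other_ion_count = integer(0),
    purity = numeric(0), score = numeric(0), coisolating = list()
  )
  if (nrow(feats) == 0L) {
    return(dplyr::bind_cols(feats[, c("feature_id", "monoisotopic_mass",
                                      "ion_count", "relative_abundance")],
                            win_cols))
  }
  rows <- purrr::map(feats$feature_id, function(fid) {
    w <- score_windows(assignments, ions, fid, window_width = window_width,
                       center_grid_step = center_grid_step, gamma = gamma,
                       annotate_top = 1L)
    if (nrow(w) > 0 && w$purity[1] >= min_purity) {
      dplyr::mutate(w[1, ], has_window = TRUE, .before = 1)
    } else {
      tibble::tibble(has_window = FALSE, center_mz = NA_real_,
                     width = NA_real_, target_ion_count = NA_integer_,
                     other_ion_count = NA_integer_, purity = NA_real_,
                     score = NA_real_, coisolating = list(NULL))
    }
  })
  dplyr::bind_cols(
    feats[, c("feature_id", "monoisotopic_mass", "ion_count",
              "relative_abundance")],
    dplyr::bind_rows(rows)
  )
}
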