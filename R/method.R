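# Chronological MS2 acquisition method generation.

#' Convert a bin assignment into chronological acquisition events
#'
#' Bin edges become event times through the probe scan rate
#' (`time = position / probe_rate`). Each event carries its target's
#' isolation window; targets below `mode_threshold` are acquired in ensemble
#' mode, heavier targets in individual-ion (i2ms) mode, with per-mode default
#' collision settings.
#'
#' @param assignment A [allocate_bins()] result.
#' @param targets A [select_targets()] table providing `feature_id`,
#'   `monoisotopic_mass`, `center_mz`, `width` for every assigned target.
#' @param geometry A [scan_geometry()].
#' @param mode_threshold Mass (Da) splitting ensemble from i2ms detection.
#' @param nce_ensemble Normalized collision energy for ensemble events.
#' @param ce_i2ms Collision energy (eV) for i2ms events.
#' @return Tibble of events sorted by start time: `target_feature_id`,
#'   `start_time`, `end_time` (s), `center_mz`, `isolation_width`,
#'   `collision_energy`, `detection_mode`.
#' @export
acquisition_events <- function(assignment, targets, geometry,
                               mode_threshold = 17000,
                               nce_ensemble = 30, ce_i2ms = 10) {
  stopifnot(inherits(geometry, "pims_geometry"))
  need <- unique(assignment$feature_id)
  tinfo <- targets[match(need, targets$feature_id), ]
  missing_win <- need[is.na(tinfo$feature_id) |
                        is.na(tinfo$center_mz) |
                        (!is.null(tinfo$has_window) & !tinfo$has_window)]
  if (length(missing_win) > 0L) {
    rlang::abort(sprintf("Target(s) without an isolation window: %s.",
                         paste(missing_win, collapse = ", ")),
                 class = "pimsr_missing_window")
  }
  idx <- match(assignment$feature_id, targets$feature_id)
  mass <- targets$monoisotopic_mass[idx]
  mode <- ifelse(mass < mode_threshold, "ensemble", "i2ms")
  out <- tibble::tibble(
    target_feature_id = assignment$feature_id,
    start_time = assignment$bin_start / geometry$probe_rate,
    end_time = assignment$bin_end / geometry$probe_rate,
    center_mz = targets$center_mz[idx],
    isolation_width = targets$width[idx],
    collision_energy = ifelse(mode == "ensemble", nce_ensemble, ce_i2ms),
    detection_mode = mode
  )
  out[order(out$start_time), ]
}

#' Write an acquisition method CSV
#'
#' Neutral, instrument-agnostic schema (columns `start_time_min`,
#' `end_time_min`, `center_mz`, `isolation_width`, `ce`, `mode`,
#' `target_id`), RFC-4180 quoting, 2-decimal minutes and 4-decimal m/z;
#' byte-stable for identical input. The table is meant to be imported into a
#' vendor targeted-MS2 method editor.
#'
#' @param events An [acquisition_events()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_method_csv <- function(events, path) {
  df <- tibble::tibble(
    start_time_min = sprintf("%.2f", events$start_time / 60),
    end_time_min = sprintf("%.2f", events$end_time / 60),
    center_mz = sprintf("%.4f", events$center_mz),
    isolation_width = format(events$isolation_width, trim = TRUE),
    ce = format(events$collision_energy, trim = TRUE),
    mode = events$detection_mode,
    target_id = events$target_feature_id
  )
  if (nrow(events) == 0L) df <- df[0, ]
  tryCatch(
    readr::write_csv(df, path, quote = "needed", eol = "\n", progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Failed writing method CSV to '%s': %s",
                           path, conditionMessage(e)),
                   class = "pimsr_io_error")
    }
  )
  invisible(path)
}

#' Read an acquisition method CSV back into events
#'
#' @param path A file written by [write_method_csv()].
#' @return Events tibble with times in seconds.
#' @export
read_method_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    target_feature_id = as.character(df$target_id),
    start_time = df$start_time_min * 60,
    end_time = df$end_time_min * 60,
    center_mz = df$center_mz,
    isolation_width = df$isolation_width,
    collision_energy = df$ce,
    detection_mode = as.character(df$mode)
  )
}
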