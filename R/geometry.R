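#' Probe scan geometry
#'
#' Describes the constant lateral motion of the sampling probe relative to
#' the mass-spectral acquisition clock. The along-track coordinate of MS scan
#' `k` (0-based) is `k * probe_rate / acquisition_rate`.
#'
#' @param probe_rate Probe line-scan rate in micrometres per second.
#' @param acquisition_rate Spectral acquisition rate in spectra per second.
#' @param strip_step Across-track step between adjacent lines in micrometres.
#' @param scans_per_line Number of MS scans acquired along one line.
#' @param n_lines Number of parallel lines in the experiment.
#' @return An object of class `pims_geometry`.
#' @examples
#' geom <- scan_geometry(probe_rate = 4, acquisition_rate = 2,
#'                       strip_step = 100, scans_per_line = 500)
#' scan_coordinate(geom, 10)  # 20 um
#' @export
scan_geometry <- function(probe_rate, acquisition_rate, strip_step,
                          scans_per_line, n_lines = 1L) {
  vals <- c(probe_rate, acquisition_rate, strip_step, scans_per_line, n_lines)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("All geometry parameters must be positive and finite.",
                 class = "pimsr_invalid_input")
  }
  structure(
    list(
      probe_rate = probe_rate,
      acquisition_rate = acquisition_rate,
      strip_step = strip_step,
      scans_per_line = as.integer(scans_per_line),
      n_lines = as.integer(n_lines)
    ),
    class = "pims_geometry"
  )
}

#' @export
print.pims_geometry <- function(x, ...) {
  cat("<pims_geometry>\n")
  cat(sprintf("  probe rate        %g um/s\n", x$probe_rate))
  cat(sprintf("  acquisition rate  %g spectra/s\n", x$acquisition_rate))
  cat(sprintf("  strip step        %g um\n", x$strip_step))
  cat(sprintf("  scans per line    %d  (line length %g um)\n",
              x$scans_per_line, line_length(x)))
  cat(sprintf("  lines             %d\n", x$n_lines))
  invisible(x)
}

#' Along-track coordinate of a scan
#'
#' @param geometry A [scan_geometry()] object.
#' @param scan_index 0-based scan index (vectorised).
#' @return Coordinate(s) in micrometres.
#' @export
scan_coordinate <- function(geometry, scan_index) {
  stopifnot(inherits(geometry, "pims_geometry"))
  scan_index * geometry$probe_rate / geometry$acquisition_rate
}

#' Length of one line in micrometres
#'
#' @param geometry A [scan_geometry()] object.
#' @return Length in micrometres spanned by `scans_per_line` scans.
#' @export
line_length <- function(geometry) {
  stopifnot(inherits(geometry, "pims_geometry"))
  geometry$scans_per_line * geometry$probe_rate / geometry$acquisition_rate
}
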