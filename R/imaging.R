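# Proteoform image reconstruction from multi-line scans.

#' Build a 2-D proteoform ion image
#'
#' Finds the ions within +/- `match_ppm` of the proteoform's major isotope
#' masses and accumulates them on a pixel grid: rows are line indices
#' (across-track, pixel size = strip step) and columns are along-track bins
#' of `pixel_along` micrometres. Counts are raw: the grid sums to the number
#' of matched ions.
#'
#' @param ions Ion tibble with `neutral_mass`, `scan_index`, `line_index`.
#' @param feature One row of a [pick_features()] table.
#' @param geometry A [scan_geometry()] with `n_lines` >= 1.
#' @param pixel_along Along-track pixel size in micrometres.
#' @param match_ppm Matching tolerance in ppm.
#' @return A `pims_image`: list with integer matrix `grid` (lines x
#'   along-track pixels), `feature_id`, `pixel_along`, `pixel_across`.
#' @export
build_image <- function(ions, feature, geometry, pixel_along = 20,
                        match_ppm = 10) {
  stopifnot(inherits(geometry, "pims_geometry"), nrow(feature) == 1L,
            pixel_along > 0)
  iso <- sort(feature$isotope_masses[[1]])
  m <- ions$neutral_mass
  matched <- rep(FALSE, length(m))
  ok <- which(is.finite(m))
  if (length(ok)) {
    idx <- findInterval(m[ok], iso)
    lo <- pmax(1L, idx); hi <- pmin(length(iso), idx + 1L)
    d <- pmin(abs(m[ok] - iso[lo]), abs(m[ok] - iso[hi]))
    near <- iso[ifelse(abs(m[ok] - iso[hi]) < abs(m[ok] - iso[lo]), hi, lo)]
    matched[ok] <- d <= near * match_ppm * 1e-6
  }
  n_rows <- geometry$n_lines
  n_cols <- max(1L, as.integer(ceiling(line_length(geometry) / pixel_along)))
  grid <- matrix(0L, n_rows, n_cols)
  if (any(matched)) {
    row <- ions$line_index[matched] + 1L
    col <- pmin(n_cols,
                floor(scan_coordinate(geometry, ions$scan_index[matched]) /
                        pixel_along) + 1L)
    keep <- row >= 1L & row <= n_rows
    tb <- table(factor(row[keep], levels = seq_len(n_rows)),
                factor(col[keep], levels = seq_len(n_cols)))
    grid <- matrix(as.integer(tb), n_rows, n_cols)
  }
  structure(
    list(grid = grid, feature_id = feature$feature_id[[1]],
         pixel_along = pixel_along, pixel_across = geometry$strip_step),
    class = "pims_image"
  )
}

#' @export
print.pims_image <- function(x, ...) {
  cat(sprintf("<pims_image> %s: %d x %d px (%g x %g um), %d ions\n",
              x$feature_id, nrow(x$grid), ncol(x$grid),
              x$pixel_across, x$pixel_along, sum(x$grid)))
  invisible(x)
}

#' Two-channel overlay of proteoform images
#'
#' Normalises each image by its own maximum and pairs them as a two-channel
#' overlay (for co-localisation display). No counts are mixed across
#' channels.
#'
#' @param a,b Two [build_image()] results on identical grids.
#' @return A `pims_overlay`: list with matrices `channel_a`, `channel_b`
#'   (each scaled to max 1, or all zero) and the two feature ids.
#' @export
merge_images <- function(a, b) {
  stopifnot(inherits(a, "pims_image"), inherits(b, "pims_image"))
  if (!identical(dim(a$grid), dim(b$grid)) ||
      a$pixel_along != b$pixel_along || a$pixel_across != b$pixel_across) {
    rlang::abort("Images have different grids; cannot merge.",
                 class = "pimsr_shape_error")
  }
  norm <- function(g) if (max(g) > 0) g / max(g) else g * 0
  structure(
    list(channel_a = norm(a$grid), channel_b = norm(b$grid),
         feature_ids = c(a$feature_id, b$feature_id),
         pixel_along = a$pixel_along, pixel_across = a$pixel_across),
    class = "pims_overlay"
  )
}
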