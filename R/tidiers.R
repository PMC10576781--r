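# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-test result
#'
#' @param x A [differential_test()] result.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @method tidy pims_diff
#' @export
tidy.pims_diff <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "Q") <- NULL; attr(out, "m") <- NULL
  attr(out, "m_convention") <- NULL; attr(out, "classes") <- NULL
  out
}

#' @rdname tidy.pims_diff
#' @method glance pims_diff
#' @export
glance.pims_diff <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    n_degenerate = sum(x$degenerate),
    Q = attr(x, "Q"),
    m = attr(x, "m"),
    m_convention = attr(x, "m_convention")
  )
}

#' Tidy PCA region scores
#'
#' @param x A [pca_scores()] result.
#' @param ... Unused.
#' @return Plain tibble of scores.
#' @method tidy pims_pca
#' @export
tidy.pims_pca <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "var_explained") <- NULL
  out
}

#' @rdname tidy.pims_pca
#' @method glance pims_pca
#' @export
glance.pims_pca <- function(x, ...) {
  ve <- attr(x, "var_explained")
  tibble::tibble(n_regions = nrow(x), var_pc1 = ve[1],
                 var_pc2 = if (length(ve) >= 2) ve[2] else 0)
}

#' Tidy a mass spectrum into (mass, density) pairs
#'
#' @param x A [build_mass_spectrum()] result.
#' @param ... Unused.
#' @return Tibble `mass`, `density`.
#' @method tidy pims_spectrum
#' @export
tidy.pims_spectrum <- function(x, ...) {
  tibble::tibble(mass = x$mass_grid, density = x$density)
}

#' Tidy a bin assignment
#'
#' @param x An [allocate_bins()] result.
#' @param ... Unused.
#' @return Plain tibble of bin rows.
#' @method tidy pims_binassign
#' @export
tidy.pims_binassign <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "iterations") <- NULL; attr(out, "mode") <- NULL
  attr(out, "unassigned_bins") <- NULL
  out
}

#' @rdname tidy.pims_binassign
#' @method glance pims_binassign
#' @export
glance.pims_binassign <- function(x, ...) {
  tibble::tibble(
    n_targets = length(unique(x$feature_id)),
    n_bins_assigned = nrow(x),
    n_bins_unassigned = length(attr(x, "unassigned_bins")),
    iterations = attr(x, "iterations"),
    mode = attr(x, "mode")
  )
}

#' Tidy a proteoform image into long pixel records
#'
#' @param x A [build_image()] result.
#' @param ... Unused.
#' @return Tibble `line`, `pixel`, `x_um`, `y_um`, `count`.
#' @method tidy pims_image
#' @export
tidy.pims_image <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    line = rep(seq_len(nrow(g)), ncol(g)),
    pixel = rep(seq_len(ncol(g)), each = nrow(g)),
    x_um = (rep(seq_len(ncol(g)), each = nrow(g)) - 0.5) * x$pixel_along,
    y_um = (rep(seq_len(nrow(g)), ncol(g)) - 0.5) * x$pixel_across,
    count = as.integer(g)
  )
}
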