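# ggplot2 displays for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mass-domain spectrum
#'
#' @param object A [build_mass_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pims_spectrum
#' @export
autoplot.pims_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mass,
                                             y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Neutral mass (Da)", y = "Ion density (ions/Da)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-test result
#'
#' `-log10(p)` against log2 fold change, significant proteoforms
#' highlighted.
#'
#' @param object A [differential_test()] result.
#' @param log2fc_cut Fold-change guide lines.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pims_diff
#' @export
autoplot.pims_diff <- function(object, log2fc_cut = 0.5, ...) {
  df <- tidy(object)
  df$neglog10p <- -log10(pmax(df$p_score, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2fc_cut, log2fc_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10(p-score)",
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' Scatter plot of PCA region scores
#'
#' @param object A [pca_scores()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pims_pca
#' @export
autoplot.pims_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' Heatmap of a proteoform ion image
#'
#' @param object A [build_image()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pims_image
#' @export
autoplot.pims_image <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Along track (um)", y = "Across track (um)",
                  fill = "Ions", title = object$feature_id) +
    ggplot2::theme_minimal()
}
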