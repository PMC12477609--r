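#' Plot a spectrum
#'
#' @param object A [spectrum_tbl].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_tbl
#' @export
autoplot.spectrum_tbl <- function(object, ...) {
  unit_lab <- switch(spec_unit(object),
    absorbance = "A (AU)",
    molar_extinction = expression(epsilon ~ (M^-1 ~ cm^-1)),
    ellipticity = expression(theta ~ (mdeg)),
    molar_ellipticity = expression(Delta * epsilon ~ (M^-1 ~ cm^-1))
  )
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = unit_lab,
                  title = attr(object, "name")) +
    ggplot2::theme_minimal()
}

#' Plot group mean signatures with a +/- 1 sd ribbon
#'
#' @param summary Output of [group_summary()].
#' @return A ggplot: one line per label with a one-standard-deviation
#'   ribbon.
#' @export
plot_group_summary <- function(summary) {
  stopifnot(all(c("label", "wavelength", "mean", "sd") %in% names(summary)))
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$wavelength, .data$mean,
                               colour = .data$label, fill = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = expression(Delta * epsilon ~ (M^-1 ~ cm^-1))) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores in the PC1/PC2 plane
#'
#' @param object A `g4_pca` model.
#' @param colour Metadata column used for point colour (default the first
#'   non-sample metadata column, if any).
#' @param ... Unused.
#' @return A ggplot of the score plot with explained-variance axis labels.
#' @method autoplot g4_pca
#' @export
autoplot.g4_pca <- function(object, colour = NULL, ...) {
  df <- tidy(object, "scores")
  if (is.null(colour)) {
    cand <- setdiff(names(object$meta), "sample")
    colour <- if (length(cand) > 0) cand[1]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60")
  p <- if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_fraction[2])
    ) +
    ggplot2::theme_minimal()
}
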