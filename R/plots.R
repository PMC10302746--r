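#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot with the ppm axis reversed (NMR convention).
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot the posterior over the number of components
#'
#' @param object An `nmr_evidence` object.
#' @param ... Unused.
#' @return A ggplot bar chart of `P(K | D)`.
#' @export
autoplot.nmr_evidence <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$K), y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "number of components K", y = "P(K | D)") +
    ggplot2::theme_minimal()
}

#' Plot the apodized model/observed overlay of a deconvolution
#'
#' @param object An `nmr_deconvolution` with a fitted model (`k_map >= 1`);
#'   for `k_map = 0` the observed spectrum alone is drawn.
#' @param ... Unused.
#' @return A ggplot overlaying the display-apodized observed and MAP model
#'   spectra.
#' @export
autoplot.nmr_deconvolution <- function(object, ...) {
  if (is.null(object$overlay)) {
    return(autoplot.nmr_spectrum(object$spectrum))
  }
  long <- tidyr::pivot_longer(object$overlay, c("observed", "model"),
                              names_to = "trace", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ppm, y = .data$intensity,
                                     colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Marginal posterior histograms per component and parameter
#'
#' @param samples A (relabeled) `posterior_draws` object.
#' @param bins Number of histogram bins (default 60).
#' @return A faceted ggplot of the marginal posteriors.
#' @export
plot_marginals <- function(samples, bins = 60) {
  stopifnot(inherits(samples, "posterior_draws"))
  long <- tidy(samples)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$parameter, .data$component),
      scales = "free", labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = NULL, y = "draws") +
    ggplot2::theme_minimal()
}
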