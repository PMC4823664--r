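#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mixture classification
#'
#' Draws the two single-odor curves and the mixture curve on a
#' log-concentration axis, with the classified regions shaded along the top.
#'
#' @param object A `mixture_classification` from [classify_mixture()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mixture_classification <- function(object, ...) {
  curves <- object$curves
  regions <- dplyr::filter(object$regions, .data$n_points > 1)
  ggplot2::ggplot(curves, ggplot2::aes(.data$conc, .data$response,
                                       color = .data$curve)) +
    ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$conc_min, xmax = .data$conc_max,
                   fill = .data$label),
      ymin = -Inf, ymax = Inf, alpha = 0.12
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response",
                  color = NULL, fill = "behavior",
                  title = paste("asymptotic behavior:",
                                as.character(object$asymptotic))) +
    ggplot2::theme_minimal()
}

#' Plot a behavior phase map
#'
#' @param object A `phase_map` tibble from [phase_map()].
#' @param ... Unused.
#' @return A ggplot raster of behavior labels over the swept parameters.
#' @export
autoplot.phase_map <- function(object, ...) {
  axes <- setdiff(names(object), "label")
  ggplot2::ggplot(object, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      suppression = "orange", inhibition = "cyan3", synergy = "green3",
      hypoadditivity = "grey60", overshadowing = "purple"
    ), drop = FALSE) +
    ggplot2::labs(fill = "behavior") +
    ggplot2::theme_minimal()
}

#' Plot a single-odor fit
#'
#' @param object An `osn_fit` from [fit_single_odor()].
#' @param ... Unused.
#' @return A ggplot with the data points and the fitted curve.
#' @export
autoplot.osn_fit <- function(object, ...) {
  dd <- object$data
  grid <- 10^seq(log10(min(dd$conc[dd$conc > 0])), log10(max(dd$conc)),
                 length.out = 200)
  fitcurve <- response_curve(object$params, grid, object$f_max)
  ggplot2::ggplot(dd, ggplot2::aes(.data$conc, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitcurve, color = "red3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response") +
    ggplot2::theme_minimal()
}

#' Plot the coverage region of a basis in the (n, eta) plane
#'
#' Shades the set of `(n, eta)` combinations representable by a basis of
#' three primary responses, evaluated on a grid.
#'
#' @param basis List of three [odor()] triples.
#' @param n_range,eta_range Plot ranges (length 2).
#' @param resolution Grid resolution per axis.
#' @return A ggplot.
#' @export
plot_hull_coverage <- function(basis, n_range, eta_range, resolution = 80) {
  grid <- tidyr::expand_grid(
    n = seq(n_range[1], n_range[2], length.out = resolution),
    eta = seq(eta_range[1], eta_range[2], length.out = resolution)
  )
  grid$covered <- hull_coverage(basis, grid$n, grid$eta)
  verts <- odor_table(basis)
  ggplot2::ggplot(grid, ggplot2::aes(.data$n, .data$eta)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$covered), alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "pink", `FALSE` = "white")) +
    ggplot2::geom_point(data = verts, color = "red3", size = 2) +
    ggplot2::labs(fill = "representable") +
    ggplot2::theme_minimal()
}
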