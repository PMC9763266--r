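#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attenuation spectrum
#'
#' Attenuation versus energy with optional K-edge reference lines, the
#' standard way ROI spectra are inspected for absorption steps.
#'
#' @param object An [attenuation_spectrum()].
#' @param edges Optional element symbols whose K-edge energies are drawn
#'   as dashed reference lines.
#' @param table An [element_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attenuation_spectrum <- function(object, edges = NULL,
                                          table = element_table(), ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_kev, y = .data$mu)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Energy (keV)", y = expression(mu ~ (mm^-1)))
  if (!is.null(edges)) {
    ek <- table$k_edge_kev[match(edges, table$symbol)]
    p <- p + ggplot2::geom_vline(xintercept = ek, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a calibration curve
#'
#' Phase measurements with across-slice standard-deviation error bars and
#' the fitted line converting edge height to concentration.
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  df <- object$measurements
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                   y = .data$mean_delta_mu0)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_delta_mu0 - .data$sd_delta_mu0,
      ymax = .data$mean_delta_mu0 + .data$sd_delta_mu0), width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "Concentration (mg/ml)",
      y = expression(Delta * mu[0] ~ (mm^-1)),
      title = sprintf("%s: slope %.3g, R² %.4f", object$element,
                      object$slope, object$r_squared))
}

#' Plot a map slice as a raster
#'
#' One z slice of a KES map, edge-height map or concentration volume.
#'
#' @param x An `element_map`, `edge_height_map` or `concentration_volume`.
#' @param z Slice index.
#' @return A ggplot.
#' @export
plot_map_slice <- function(x, z = 1L) {
  arr <- if (inherits(x, "element_map")) x$delta_mu
  else if (inherits(x, "edge_height_map")) x$delta_mu0
  else if (inherits(x, "concentration_volume")) x$concentration
  else stop("unsupported map type")
  lab <- if (inherits(x, "concentration_volume")) "mg/ml" else "mm^-1"
  sl <- arr[z, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.vector(sl[cbind(df$y, df$x)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s, slice %d", x$element, z))
}

#' Plot a concentration histogram
#'
#' @param h A [concentration_histogram()] result.
#' @return A ggplot.
#' @export
plot_concentration_histogram <- function(h) {
  ggplot2::ggplot(h$histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = h$histogram$bin_hi[1] - h$histogram$bin_lo[1]) +
    ggplot2::labs(x = "Concentration (mg/ml)", y = "Voxels")
}
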