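#' Tidiers and plots for fitted objects
#'
#' Broom-style `tidy()`/`glance()` methods and `autoplot()` visualizations
#' for the probability surface, the calibration fit and the knotting curve.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.probability_surface <- function(x, ...) {
  dplyr::mutate(x$data,
                p_fit = surface_probability(x, .data$n_beads, .data$g,
                                            warn_extrapolation = FALSE))
}

#' @rdname tidiers
#' @export
glance.probability_surface <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(td),
    n_min = x$n_range[1], n_max = x$n_range[2],
    g_min = x$g_range[1], g_max = x$g_range[2],
    span = x$span, degree = x$degree,
    rmse = sqrt(mean((td$p_fit - td$p_knot)^2)),
    p_max = max(td$p_knot)
  )
}

#' @rdname tidiers
#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(
    term = c("g", "d"),
    estimate = c(x$g, x$d),
    unit = c("dimensionless", "nm")
  )
}

#' @rdname tidiers
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    g = x$g, d = x$d, error = x$error, l_p_nm = x$l_p_nm,
    n_targets = nrow(x$targets),
    n_starts = nrow(x$trace), n_converged = sum(x$trace$converged),
    under_determined = x$under_determined
  )
}

#' @rdname tidiers
#' @export
autoplot.probability_surface <- function(x, ...) {
  grid <- tidyr::expand_grid(
    n_beads = seq(x$n_range[1], x$n_range[2], length.out = 60),
    g = seq(x$g_range[1], x$g_range[2], length.out = 60))
  grid$p <- surface_probability(x, grid$n_beads, grid$g,
                                warn_extrapolation = FALSE)
  ggplot2::ggplot(grid, ggplot2::aes(.data$n_beads, .data$g)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p)) +
    ggplot2::geom_point(data = x$data, shape = 21, colour = "white",
                        ggplot2::aes(fill = .data$p_knot)) +
    ggplot2::scale_fill_viridis_c(name = "P(knot)") +
    ggplot2::labs(x = "chain length N (beads)", y = "stiffness g",
                  title = "Knotting-probability surface") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.knotting_curve <- function(x, ...) {
  b0 <- attr(x, "B0")
  p <- ggplot2::ggplot(x, ggplot2::aes(.data$bp, .data$p_knot)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p_knot - .data$se,
                                          ymax = .data$p_knot + .data$se)) +
    ggplot2::labs(x = "DNA length (bp)", y = "P(knot)",
                  title = "Knotting probability vs DNA length") +
    ggplot2::theme_minimal()
  if (is.finite(b0))
    p <- p + ggplot2::geom_vline(xintercept = b0, linetype = "dashed") +
      ggplot2::annotate("text", x = b0, y = max(x$p_knot),
                        label = sprintf("B0 = %.3g bp", b0), hjust = -0.1)
  p
}

#' Plot a knot-size distribution
#'
#' @param stats A result of [knot_size_stats()].
#' @return A ggplot object.
#' @export
plot_knot_sizes <- function(stats) {
  ggplot2::ggplot(stats$sizes, ggplot2::aes(.data$size_beads)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prob), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$prob_smooth), colour = "red") +
    ggplot2::geom_vline(xintercept = stats$mode_size, linetype = "dashed") +
    ggplot2::labs(x = "knot contour length (beads)", y = "probability",
                  title = "Trefoil size distribution") +
    ggplot2::theme_minimal()
}
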