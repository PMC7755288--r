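#' Plot a spherical power spectrum
#'
#' Bar chart of the mode powers `||F_l||^2` against degree `l`; the balance
#' between `l = 1` and `l = 2` distinguishes vectorial from nematic patterns.
#'
#' @param object A `sph_power_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sph_power_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$l, y = .data$power)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "spherical-harmonic degree l",
                  y = expression("||" * F[l] * "||"^2)) +
    ggplot2::theme_minimal()
}

#' Mollweide map of a surface pattern
#'
#' Equal-area map of the pattern samples, colored by density value.
#'
#' @inheritParams validate_surface_pattern
#' @return A ggplot object.
#' @export
plot_mollweide <- function(pattern) {
  validate_surface_pattern(pattern)
  mc <- mollweide_coords(pattern)
  mc$value <- pattern$value
  tt <- seq(0, 2 * pi, length.out = 181)
  edge <- data.frame(x = 2 * sqrt(2) * cos(tt), y = sqrt(2) * sin(tt))
  ggplot2::ggplot(mc, ggplot2::aes(x = .data$mx, y = .data$my,
                                   color = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_path(data = edge,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, color = "grey50") +
    ggplot2::coord_fixed() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::theme_void()
}

#' Plot a COOP-versus-coupling sweep
#'
#' Lines for the four co-orientational order parameters as a function of the
#' coupling strength.
#'
#' @param object A `coop_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("co_S", "co_P", "co_D", "co_C"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value,
                                     color = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda), y = "COOP") +
    ggplot2::theme_minimal()
}

#' Plot co-orientational order parameters with uncertainty
#'
#' @param object A `coop_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coop_result <- function(object, ...) {
  est <- object$estimates
  est$parameter <- factor(est$parameter, levels = est$parameter)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$parameter, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "co-orientational order parameter") +
    ggplot2::theme_minimal()
}
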