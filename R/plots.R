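#' Raster plot of a spike record
#'
#' @param spikes Spike tibble (`t_ms`, `neuron_id`, `population`) or an
#'   `eicrit_sim`.
#' @param max_points Subsample cap for very dense records.
#' @return A ggplot.
#' @export
plot_raster <- function(spikes, max_points = 2e5) {
  if (inherits(spikes, "eicrit_sim")) spikes <- spikes$spikes
  if (nrow(spikes) > max_points)
    spikes <- spikes[sort(sample.int(nrow(spikes), max_points)), ]
  ggplot2::ggplot(spikes,
                  ggplot2::aes(x = .data$t_ms, y = .data$neuron_id,
                               colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Population-rate series plot
#'
#' @param sim An `eicrit_sim` (or a series tibble with `t_ms`,
#'   `rate_E_hz`, `rate_I_hz`).
#' @return A ggplot.
#' @export
plot_series <- function(sim) {
  ser <- if (inherits(sim, "eicrit_sim")) sim$series else sim
  long <- tidyr::pivot_longer(ser[c("t_ms", "rate_E_hz", "rate_I_hz")],
                              -"t_ms", names_to = "population",
                              values_to = "rate_hz")
  long$population <- ifelse(long$population == "rate_E_hz", "E", "I")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_ms, y = .data$rate_hz,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "rate (Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eicrit_sim <- function(object, ...) plot_series(object)

#' Nullcline plot of the rate model
#'
#' @param nc Output of [nullclines()].
#' @param fixed_points Optional [find_fixed_points()] result to overlay.
#' @return A ggplot.
#' @export
plot_nullclines <- function(nc, fixed_points = NULL) {
  long <- tidyr::pivot_longer(
    nc, c("rho_I_exc_nullcline", "rho_I_inh_nullcline"),
    names_to = "branch", values_to = "rho_I")
  long$branch <- ifelse(long$branch == "rho_I_exc_nullcline",
                        "excitatory", "inhibitory")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rho_E, y = .data$rho_I,
                                          colour = .data$branch)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = expression(rho[E] ~ "(Hz)"),
                  y = expression(rho[I] ~ "(Hz)"), colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fixed_points) && nrow(fixed_points))
    p <- p + ggplot2::geom_point(
      data = fixed_points, inherit.aes = FALSE,
      ggplot2::aes(x = .data$rho_E, y = .data$rho_I,
                   shape = .data$classification), size = 3)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.avalanche_catalog <- function(object, ...) {
  x <- sort(unique(object$size))
  ccdf <- vapply(x, function(v) mean(object$size >= v), numeric(1))
  ggplot2::ggplot(tibble::tibble(size = x, ccdf = ccdf),
                  ggplot2::aes(x = .data$size, y = .data$ccdf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "avalanche size", y = "P(S >= s)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.shape_collapse <- function(object, ...) {
  ggplot2::ggplot(object$shapes,
                  ggplot2::aes(x = .data$s, y = .data$value,
                               colour = factor(.data$duration_bins))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t / T", y = "rescaled profile",
                  colour = "T (bins)") +
    ggplot2::theme_minimal()
}
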