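#' Tidy summaries of fitted objects
#'
#' Broom-style one-row-per-term tibbles for the package's estimator
#' objects, and `glance()` one-row model summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name eicrit-tidiers
NULL

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = "exponent", estimate = x$exponent,
                 std.error = x$se)
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::glance
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, std.error = x$se, xmin = x$xmin,
                 n_tail = x$n_tail, ks = x$ks, method = x$method)
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.size_duration_fit <- function(x, ...) {
  tibble::tibble(term = "log(duration)", estimate = x$slope,
                 std.error = x$se)
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.branching_estimate <- function(x, ...) {
  tibble::tibble(term = "branching_ratio", estimate = x$sigma,
                 n = x$n_pairs, method = x$method)
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.bt_residuals <- function(x, ...) {
  tibble::tibble(term = c("slope_residual", "intercept_residual", "deltaW"),
                 estimate = c(x$slope_residual, x$intercept_residual,
                              x$deltaW))
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.lna_variances <- function(x, ...) {
  tibble::tibble(term = c("var_e", "var_i", "cov_ei",
                          "scaled_var_e", "scaled_var_i", "distance"),
                 estimate = c(x$var_e, x$var_i, x$cov_ei,
                              x$scaled_var_e, x$scaled_var_i, x$distance))
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::tidy
tidy.mf_fixed_points <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname eicrit-tidiers
#' @exportS3Method generics::glance
glance.eicrit_sim <- function(x, ...) {
  tibble::tibble(n_exc = x$n_exc, n_inh = x$n_inh,
                 duration_ms = x$duration_ms, dt = x$dt,
                 n_spikes = nrow(x$spikes),
                 rate_E_hz = mean(x$series$rate_E_hz),
                 rate_I_hz = mean(x$series$rate_I_hz))
}
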