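#' Homogeneous Poisson spike trains
#'
#' Independent Poisson trains with known rate: the ground-truth fixture
#' for rate estimators, ISI statistics (CV = 1) and the binned series
#' (counts are Poisson with mean `rate * bin`).
#'
#' @param rate_hz Rate per train (Hz).
#' @param duration_ms Duration (ms).
#' @param n_trains Number of independent trains.
#' @param seed Integer seed (`NULL`: caller's stream).
#' @return Tibble `t_ms`, `neuron_id` (train index), `population`
#'   (`"E"`), sorted by time.
#' @export
poisson_train <- function(rate_hz, duration_ms, n_trains = 1, seed = NULL) {
  stopifnot(rate_hz >= 0, duration_ms > 0, n_trains >= 1)
  with_seed(seed, {
    counts <- rpois(n_trains, rate_hz * duration_ms * 1e-3)
    out <- tibble::tibble(
      t_ms = runif(sum(counts), 0, duration_ms),
      neuron_id = rep(seq_len(n_trains), counts),
      population = "E")
    dplyr::arrange(out, .data$t_ms)
  })
}

#' Galton-Watson avalanche fixture
#'
#' Branching-process avalanches with a known branching ratio and a known
#' catalog: each avalanche starts from one ancestor; every individual in
#' generation `g` has `Poisson(sigma)` offspring in generation `g + 1`;
#' each generation occupies one time bin of `bin_ms` and its events are
#' placed uniformly inside the bin; avalanches are separated by
#' `gap_bins` empty bins so that any detector binning at `<= bin_ms *
#' gap_bins` recovers the true segmentation. At `sigma = 1` sizes follow
#' the critical branching power law (exponent 3/2).
#'
#' @param n_avalanches Number of avalanches.
#' @param sigma Mean offspring count (branching ratio).
#' @param bin_ms Generation duration (ms).
#' @param gap_bins Empty bins between avalanches.
#' @param max_generations Safety cap on avalanche duration; avalanches
#'   hitting it are truncated (flagged in the truth table). A critical
#'   cascade surviving to generation `g` has size of order `g^2`, so keep
#'   the cap moderate.
#' @param seed Integer seed.
#' @return List `events` (tibble `t_ms`), `truth` (tibble `id`, `size`,
#'   `duration_bins`, `truncated`), `sigma`, `bin_ms`.
#' @export
branching_avalanches <- function(n_avalanches, sigma = 1, bin_ms = 5,
                                 gap_bins = 3, max_generations = 1000,
                                 seed = NULL) {
  stopifnot(n_avalanches >= 1, sigma >= 0, bin_ms > 0, gap_bins >= 2)
  with_seed(seed, {
    t0 <- 0
    ev <- vector("list", n_avalanches)
    truth <- vector("list", n_avalanches)
    for (a in seq_len(n_avalanches)) {
      gens <- integer(0)
      n <- 1L
      while (n > 0L && length(gens) < max_generations) {
        gens <- c(gens, n)
        n <- sum(rpois(n, sigma))
      }
      times <- unlist(purrr::map2(seq_along(gens), gens, function(g, k) {
        runif(k, t0 + (g - 1) * bin_ms, t0 + g * bin_ms)
      }))
      ev[[a]] <- times
      truth[[a]] <- tibble::tibble(id = a, size = sum(gens),
                                   duration_bins = length(gens),
                                   truncated = n > 0L)
      t0 <- t0 + (length(gens) + gap_bins) * bin_ms
    }
    list(events = tibble::tibble(t_ms = sort(unlist(ev))),
         truth = dplyr::bind_rows(truth), sigma = sigma, bin_ms = bin_ms)
  })
}

#' Samples from a discrete power law
#'
#' Inverse-CDF sampling from `P(X = k) ~ k^-exponent`, `k >= xmin`. The
#' CDF is tabulated exactly up to `cap`; the small tail mass beyond it is
#' drawn from the continuous Pareto approximation and rounded, which is
#' accurate to well under the estimator tolerances for `exponent > 1.2`.
#' Fixture for [fit_power_law()].
#'
#' @param n Sample size.
#' @param exponent Density exponent (> 1).
#' @param xmin Lower cutoff.
#' @param cap Exact-tabulation upper bound.
#' @param seed Integer seed.
#' @return Numeric vector of integer-valued samples.
#' @export
power_law_samples <- function(n, exponent, xmin = 1, cap = 10000,
                              seed = NULL) {
  stopifnot(n >= 1, exponent > 1, xmin >= 1, cap > xmin)
  z <- hurwitz_zeta(exponent, xmin)
  k <- xmin:cap
  Fk <- cumsum(k^(-exponent)) / z
  with_seed(seed, {
    u <- runif(n)
    out <- numeric(n)
    inside <- u <= Fk[length(Fk)]
    out[inside] <- k[findInterval(u[inside], c(0, Fk), rightmost.closed = TRUE)]
    if (any(!inside)) {
      # continuous Pareto tail beyond the table (numeric: heavy tails can
      # exceed integer range)
      v <- (u[!inside] - Fk[length(Fk)]) / (1 - Fk[length(Fk)])
      out[!inside] <- round((cap + 0.5) * (1 - v)^(-1 / (exponent - 1)))
    }
    out
  })
}
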