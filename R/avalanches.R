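#' Detect avalanches in an event record
#'
#' Bins pooled event times and segments the record into avalanches:
#' maximal runs of consecutive non-empty bins, separated by at least one
#' empty bin. Bins are anchored on the absolute time grid (multiples of
#' the bin width). With `bin = "auto"` the bin width is the mean
#' inter-event interval of the pooled record (the conventional choice at
#' which the branching ratio of a critical record is closest to one).
#'
#' @param events Numeric event times (ms), or a spike tibble with a
#'   `t_ms` column.
#' @param bin Bin width (ms) or `"auto"`.
#' @param t_range Optional analysis window (ms).
#' @param profiles Attach each avalanche's per-bin count vector as a
#'   list-column (needed by [shape_collapse()] and the bin-ratio
#'   branching estimator).
#' @return A tibble of class `avalanche_catalog`: `id`, `t_start_ms`,
#'   `size` (events), `duration_bins`, `duration_ms`; attribute `bin`
#'   holds the width used; optional list-column `profile`.
#' @export
detect_avalanches <- function(events, bin = "auto", t_range = NULL,
                              profiles = FALSE) {
  t <- if (is.data.frame(events)) events$t_ms else as.numeric(events)
  if (!is.null(t_range)) t <- t[t >= t_range[1] & t <= t_range[2]]
  t <- sort(t)
  empty <- tibble::tibble(id = integer(), t_start_ms = numeric(),
                          size = integer(), duration_bins = integer(),
                          duration_ms = numeric())
  if (length(t) < 2) {
    out <- structure(empty, class = c("avalanche_catalog", class(empty)))
    attr(out, "bin") <- NA_real_
    return(out)
  }
  if (identical(bin, "auto")) bin <- mean(diff(t))
  stopifnot(is.numeric(bin), bin > 0)
  # bins anchored on the absolute time grid (multiples of `bin`), so the
  # segmentation does not depend on the time of the first event
  idx <- floor(t / bin)
  idx <- idx - idx[1]
  occ <- unique(idx)
  cnt <- as.integer(table(idx))  # table of sorted unique idx, same order
  # runs of consecutive occupied bins
  brk <- c(0L, which(diff(occ) > 1L), length(occ))
  n_av <- length(brk) - 1L
  rows <- vector("list", n_av)
  for (a in seq_len(n_av)) {
    sel <- (brk[a] + 1L):brk[a + 1L]
    prof <- cnt[sel]
    rows[[a]] <- tibble::tibble(
      id = a, t_start_ms = (occ[sel[1]] + floor(t[1] / bin)) * bin,
      size = sum(prof), duration_bins = length(sel),
      duration_ms = length(sel) * bin,
      profile = if (profiles) list(prof) else NULL)
  }
  out <- dplyr::bind_rows(rows)
  out <- structure(out, class = c("avalanche_catalog", class(out)))
  attr(out, "bin") <- bin
  out
}

# generalized (Hurwitz) zeta via direct sum + Euler-Maclaurin tail
hurwitz_zeta <- function(alpha, q, K = 1000) {
  k <- 0:(K - 1)
  s <- sum((q + k)^(-alpha))
  qK <- q + K
  s + qK^(1 - alpha) / (alpha - 1) + qK^(-alpha) / 2 +
    alpha * qK^(-alpha - 1) / 12
}

powerlaw_loglik <- function(alpha, x, xmin) {
  -length(x) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

powerlaw_cdf <- function(x, alpha, xmin) {
  # P(X <= x) for the discrete power law on {xmin, xmin+1, ...};
  # expressed through the Hurwitz zeta so heavy tails need no tabulation
  z <- hurwitz_zeta(alpha, xmin)
  vapply(x, function(v) 1 - hurwitz_zeta(alpha, v + 1) / z, numeric(1))
}

fit_alpha_mle <- function(x, xmin) {
  opt <- optimize(function(a) -powerlaw_loglik(a, x, xmin),
                  interval = c(1.01, 8))
  a <- opt$minimum
  h <- 1e-4
  d2 <- (powerlaw_loglik(a + h, x, xmin) - 2 * powerlaw_loglik(a, x, xmin) +
           powerlaw_loglik(a - h, x, xmin)) / h^2
  list(alpha = a, se = if (d2 < 0) sqrt(-1 / d2) else NA_real_)
}

ks_distance <- function(x, alpha, xmin) {
  x <- sort(x[x >= xmin])
  ux <- unique(x)
  emp <- cumsum(tabulate(match(x, ux), nbins = length(ux))) / length(x)
  mod <- powerlaw_cdf(ux, alpha, xmin)
  max(abs(emp - mod))
}

#' Fit a discrete power law to avalanche sizes
#'
#' Two estimators for the exponent of `P(x) ~ x^-alpha` on integers
#' `x >= xmin`:
#' \describe{
#'   \item{`"mle"`}{Maximum likelihood under the discrete (zeta)
#'     distribution, with the generalized zeta evaluated numerically.
#'     When `xmin` is `NULL` it is chosen by minimizing the
#'     Kolmogorov-Smirnov distance between the model and the tail of the
#'     data. The standard error comes from the observed information.}
#'   \item{`"ccdf"`}{Least-squares slope of the log-log complementary
#'     CDF over `[xmin, q99]`; the density exponent is `1 - slope`.
#'     Robust for visual comparison; statistically inferior to MLE.}
#' }
#'
#' @param x Positive sizes (rounded to integers for the discrete model);
#'   or an `avalanche_catalog`, whose `size` column is used.
#' @param xmin Lower cutoff, or `NULL` to select by KS.
#' @param method `"mle"` or `"ccdf"`.
#' @param xmin_candidates Candidate cutoffs scanned when `xmin` is
#'   `NULL`.
#' @return A list of class `powerlaw_fit`: `exponent`, `se`, `xmin`,
#'   `n_tail`, `ks`, `method`, and for `"ccdf"` the regression data.
#' @export
fit_power_law <- function(x, xmin = NULL, method = c("mle", "ccdf"),
                          xmin_candidates = 1:20) {
  method <- match.arg(method)
  if (inherits(x, "avalanche_catalog")) x <- x$size
  x <- as.numeric(x[is.finite(x) & x >= 1])
  if (length(x) < 50)
    abort("too few observations for a tail fit (need >= 50)")
  xi <- pmax(round(x), 1)
  if (method == "mle") {
    if (is.null(xmin)) {
      cands <- xmin_candidates[xmin_candidates <= quantile(xi, 0.75)]
      if (!length(cands)) cands <- 1
      scans <- purrr::map(cands, function(xm) {
        xt <- xi[xi >= xm]
        if (length(xt) < 50) return(NULL)
        f <- fit_alpha_mle(xt, xm)
        list(xmin = xm, alpha = f$alpha, se = f$se,
             ks = ks_distance(xt, f$alpha, xm), n = length(xt))
      })
      scans <- purrr::compact(scans)
      if (!length(scans)) abort("no viable xmin candidate")
      best <- scans[[which.min(purrr::map_dbl(scans, "ks"))]]
    } else {
      xt <- xi[xi >= xmin]
      f <- fit_alpha_mle(xt, xmin)
      best <- list(xmin = xmin, alpha = f$alpha, se = f$se,
                   ks = ks_distance(xt, f$alpha, xmin), n = length(xt))
    }
    out <- list(exponent = best$alpha, se = best$se, xmin = best$xmin,
                n_tail = best$n, ks = best$ks, method = "mle")
  } else {
    if (is.null(xmin)) xmin <- 1
    hi <- quantile(x, 0.99)
    xs <- sort(unique(x[x >= xmin & x <= hi]))
    if (length(xs) < 5)
      abort("too few distinct sizes in the regression range")
    ccdf <- vapply(xs, function(v) mean(x >= v), numeric(1))
    fit <- lm(log(ccdf) ~ log(xs))
    sl <- coef(fit)[[2]]
    out <- list(exponent = 1 - sl, se = summary(fit)$coefficients[2, 2],
                xmin = xmin, n_tail = sum(x >= xmin), ks = NA_real_,
                method = "ccdf",
                data = tibble::tibble(x = xs, ccdf = ccdf))
  }
  class(out) <- "powerlaw_fit"
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit> exponent = ", signif(x$exponent, 4),
      " (se ", signif(x$se, 3), "), xmin = ", x$xmin,
      ", n_tail = ", x$n_tail, ", method = ", x$method, "\n", sep = "")
  invisible(x)
}

#' Branching-ratio estimators
#'
#' \describe{
#'   \item{`"bin_ratio"`}{Mean of `n(t+1)/n(t)` over consecutive bin
#'     pairs inside avalanches (the last bin of each avalanche
#'     contributes a ratio of 0 against the following empty bin when
#'     `include_last` is set, matching the convention that counts
#'     extinction).}
#'   \item{`"causal"`}{Fractional descendant counting on the raw spike
#'     times: each spike within `window` ms after spike `i` is a
#'     candidate descendant of `i` and contributes `1/a` where `a` is its
#'     number of candidate ancestors; the ratio is the mean attributed
#'     descendant count per spike (spikes too close to the record end are
#'     excluded as ancestors).}
#' }
#' Both approach 1 at criticality.
#'
#' @param events Event times (ms) or spike tibble.
#' @param method `"bin_ratio"` or `"causal"`.
#' @param bin Bin width for `"bin_ratio"` (`"auto"` = mean inter-event
#'   interval).
#' @param include_last Count the extinction step of each avalanche as a
#'   zero ratio.
#' @param window Causal window (ms), defaulting to the synaptic time
#'   constant.
#' @return A list of class `branching_estimate`: `sigma`, `n_pairs`,
#'   `method`.
#' @export
branching_ratio <- function(events, method = c("bin_ratio", "causal"),
                            bin = "auto", include_last = TRUE, window = 5) {
  method <- match.arg(method)
  t <- if (is.data.frame(events)) events$t_ms else as.numeric(events)
  t <- sort(t)
  if (method == "bin_ratio") {
    cat_ <- detect_avalanches(t, bin = bin, profiles = TRUE)
    ratios <- purrr::map(cat_$profile, function(p) {
      r <- if (length(p) > 1) p[-1] / p[-length(p)] else numeric(0)
      if (include_last) c(r, 0) else r
    })
    ratios <- unlist(ratios)
    if (!length(ratios)) abort("no bin pairs available")
    out <- list(sigma = mean(ratios), n_pairs = length(ratios),
                method = method, bin = attr(cat_, "bin"))
  } else {
    stopifnot(window > 0)
    n <- length(t)
    if (n < 3) abort("too few events")
    # number of candidate ancestors of each event
    lo <- findInterval(t - window, t)           # events with time <= t - w
    anc <- (seq_len(n) - 1L) - lo               # strictly earlier, within w
    credit <- numeric(n)
    ok <- which(anc > 0)
    for (j in ok) {
      credit[(lo[j] + 1L):(j - 1L)] <- credit[(lo[j] + 1L):(j - 1L)] +
        1 / anc[j]
    }
    keep <- t <= t[n] - window            # full observation window
    if (!any(keep)) abort("record shorter than the causal window")
    out <- list(sigma = mean(credit[keep]), n_pairs = sum(keep),
                method = method, window = window)
  }
  class(out) <- "branching_estimate"
  out
}

#' @export
print.branching_estimate <- function(x, ...) {
  cat("<branching_estimate> sigma = ", signif(x$sigma, 4),
      " (", x$method, ", n = ", x$n_pairs, ")\n", sep = "")
  invisible(x)
}

#' Coefficient of variation of inter-spike intervals
#'
#' Per-neuron CV of the inter-spike intervals, averaged over neurons with
#' at least `min_spikes` spikes (CV near 1: Poisson-like irregular
#' firing; near 0: clock-like).
#'
#' @param spikes Spike tibble (`t_ms`, `neuron_id`).
#' @param min_spikes Minimum spikes per neuron to enter the average.
#' @return List `cv_mean`, `n_neurons`, and the per-neuron tibble `cv`.
#' @export
isi_cv <- function(spikes, min_spikes = 5) {
  per <- spikes |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::filter(dplyr::n() >= min_spikes) |>
    dplyr::summarise(cv = {
      d <- diff(sort(.data$t_ms))
      sd(d) / mean(d)
    }, .groups = "drop")
  if (nrow(per) == 0) abort("no neuron reaches the minimum spike count")
  list(cv_mean = mean(per$cv), n_neurons = nrow(per), cv = per)
}

#' Avalanche shape collapse
#'
#' Rescales each avalanche's temporal profile to unit duration and scales
#' the amplitude by `T^(gamma - 1)`; at criticality a single exponent
#' collapses all durations onto one universal scaling shape. The collapse
#' quality is the mean squared deviation of the per-duration mean
#' profiles from their grand mean on a common grid; the reported
#' `gamma` minimizes it over `gamma_grid`.
#'
#' @param catalog An `avalanche_catalog` with profiles (see
#'   [detect_avalanches()]).
#' @param gamma_grid Candidate scaling exponents.
#' @param durations Bin-count durations to use (defaults to all with at
#'   least `min_count` avalanches and duration >= 4 bins).
#' @param min_count Minimum avalanches per duration.
#' @param n_grid Common time grid resolution.
#' @return A list of class `shape_collapse`: `gamma`, `objective` (tibble
#'   `gamma`, `msd`), and `shapes` (tibble `duration_bins`, `s` in
#'   `[0,1]`, `value` at the best exponent).
#' @export
shape_collapse <- function(catalog, gamma_grid = seq(1.1, 2.5, by = 0.02),
                           durations = NULL, min_count = 10, n_grid = 21) {
  if (!"profile" %in% names(catalog))
    abort("catalog lacks profiles; rerun detect_avalanches(profiles = TRUE)")
  tab <- table(catalog$duration_bins)
  if (is.null(durations)) {
    durations <- as.integer(names(tab)[tab >= min_count])
    durations <- durations[durations >= 4]
  }
  if (length(durations) < 3)
    abort("need at least 3 eligible durations for a collapse")
  sgrid <- seq(0, 1, length.out = n_grid)
  mean_profiles <- purrr::map(durations, function(Tb) {
    profs <- catalog$profile[catalog$duration_bins == Tb]
    m <- Reduce(`+`, profs) / length(profs)
    approx(seq(0, 1, length.out = Tb), m, xout = sgrid)$y
  })
  msd <- purrr::map_dbl(gamma_grid, function(g) {
    # profile amplitude grows as T^(gamma-1): undo it with T^(1-gamma)
    scaled <- purrr::map2(mean_profiles, durations, ~ .x * .y^(1 - g))
    M <- do.call(rbind, scaled)
    M <- M / mean(M)               # overall scale is not identified
    mean(apply(M, 2, var))
  })
  g_best <- gamma_grid[which.min(msd)]
  shapes <- purrr::map2_dfr(mean_profiles, durations, function(m, Tb) {
    tibble::tibble(duration_bins = Tb, s = sgrid,
                   value = m * Tb^(1 - g_best))
  })
  structure(list(gamma = g_best,
                 objective = tibble::tibble(gamma = gamma_grid, msd = msd),
                 shapes = shapes),
            class = "shape_collapse")
}

#' Size-duration scaling of avalanches
#'
#' Log-log regression of mean size against duration; at mean-field
#' criticality the slope (`1/(sigma nu z)`) is 2, consistent with size
#' exponent 3/2 and duration exponent 2 through the scaling relation
#' `(tau_t - 1)/(tau_s - 1) = slope`.
#'
#' @param catalog An `avalanche_catalog`.
#' @param min_count Minimum avalanches per duration bin.
#' @return A list of class `size_duration_fit`: `slope`, `se`, and the
#'   per-duration means.
#' @export
size_duration_scaling <- function(catalog, min_count = 5) {
  agg <- catalog |>
    dplyr::group_by(.data$duration_bins) |>
    dplyr::summarise(mean_size = mean(.data$size), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_count, .data$duration_bins >= 1)
  if (nrow(agg) < 4) abort("too few duration bins for a scaling fit")
  fit <- lm(log(mean_size) ~ log(duration_bins), data = agg)
  structure(list(slope = coef(fit)[[2]],
                 se = summary(fit)$coefficients[2, 2],
                 data = agg),
            class = "size_duration_fit")
}
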