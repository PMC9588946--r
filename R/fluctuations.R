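#' Two-population birth-death Markov model
#'
#' Stochastic population-activity model underlying the rate equations:
#' counts `n_E`, `n_I` of active units gain one unit at rate
#' `N_x * alpha * G(z_x)` and lose one at rate `alpha * n_x`, with
#' intensive activities `e = n_E/N_E`, `i = n_I/N_I` entering the gain
#' through `z_x = c_xE e + c_xI i + drive_x`. The deterministic limit is
#' the two-population rate model; finite `N` adds demographic noise whose
#' stationary covariance diverges as the linearization approaches
#' criticality.
#'
#' @param N_E,N_I System sizes (noise scale; variances of the intensive
#'   activities scale as 1/N).
#' @param alpha Relaxation rate (per ms); default `1/tau_m`.
#' @param coupling Named coefficients `c(c_EE, c_EI, c_IE, c_II)` (e.g.
#'   from [coupling_coefficients()]).
#' @param drive Named external inputs `c(E=, I=)` in gain-input units.
#' @param gp A [gain_params()].
#' @return A list of class `markov_config`.
#' @export
markov_config <- function(N_E, N_I = round(N_E / 4), alpha = 1 / 20,
                          coupling, drive, gp = gain_params()) {
  stopifnot(N_E >= 1, N_I >= 1, alpha > 0,
            all(c("c_EE", "c_EI", "c_IE", "c_II") %in% names(coupling)))
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I), alpha = alpha,
                 coupling = coupling[c("c_EE", "c_EI", "c_IE", "c_II")],
                 drive = c(E = unname(drive[["E"]]), I = unname(drive[["I"]])),
                 gp = gp),
            class = "markov_config")
}

# slope of the gain at input z (central difference)
gain_slope <- function(z, gp, h = 1e-4) {
  (gain(z + h, gp) - gain(z - h, gp)) / (2 * h)
}

#' Deterministic fixed point of the Markov model
#'
#' Solves `e = G(c_EE e + c_EI i + drive_E)`, `i = G(c_IE e + c_II i +
#' drive_I)` by damped Newton iteration from `init`.
#'
#' @param config A [markov_config()].
#' @param init Starting activities `c(e, i)`.
#' @return Named numeric `c(e, i)`.
#' @export
markov_fixed_point <- function(config, init = c(e = 1, i = 1)) {
  cc <- config$coupling; gp <- config$gp; dr <- config$drive
  Fv <- function(x) {
    zE <- cc[["c_EE"]] * x[1] + cc[["c_EI"]] * x[2] + dr[["E"]]
    zI <- cc[["c_IE"]] * x[1] + cc[["c_II"]] * x[2] + dr[["I"]]
    c(gain(zE, gp) - x[1], gain(zI, gp) - x[2])
  }
  x <- pmax(as.numeric(init), 0)
  # damped relaxation first (globally convergent for the relaxational
  # dynamics when the fixed point is stable), then Newton polish
  for (it in 1:2000) {
    f0 <- Fv(x)
    if (max(abs(f0)) < 1e-9) break
    x <- pmax(x + 0.2 * pmin(pmax(f0, -50), 50), 0)
  }
  for (it in 1:100) {
    f0 <- Fv(x)
    if (max(abs(f0)) < 1e-11) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- max(1e-6, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      J[, j] <- (Fv(xp) - f0) / h
    }
    st <- tryCatch(solve(J, f0), error = function(e) f0)
    st <- pmin(pmax(st, -gp$rmax / 4), gp$rmax / 4)
    x <- pmax(x - st, 0)
  }
  if (max(abs(Fv(x))) > 1e-6)
    abort("fixed-point iteration did not converge")
  c(e = x[1], i = x[2])
}

# drift linearization A and diffusion B (intensive variables) at activities x
lna_matrices <- function(config, x) {
  cc <- config$coupling; gp <- config$gp; dr <- config$drive; a <- config$alpha
  zE <- cc[["c_EE"]] * x[1] + cc[["c_EI"]] * x[2] + dr[["E"]]
  zI <- cc[["c_IE"]] * x[1] + cc[["c_II"]] * x[2] + dr[["I"]]
  sE <- gain_slope(zE, gp); sI <- gain_slope(zI, gp)
  A <- a * matrix(c(sE * cc[["c_EE"]] - 1, sE * cc[["c_EI"]],
                    sI * cc[["c_IE"]], sI * cc[["c_II"]] - 1),
                  2, 2, byrow = TRUE)
  B <- diag(c(2 * a * x[1] / config$N_E, 2 * a * x[2] / config$N_I))
  list(A = A, B = B)
}

#' Linear-noise (van Kampen) stationary covariance
#'
#' Linearizes the birth-death dynamics at the deterministic fixed point and
#' solves the stationary Lyapunov equation `A S + S A' = -B` with
#' diffusion `B = diag(2 alpha e*/N_E, 2 alpha i*/N_I)`. The returned
#' `scaled_var_*` entries (`N * var`) are size-independent and diverge as
#' the linearization loses stability, which is the fluctuation signature
#' of approaching criticality; `distance` reports `min |Re(eigen(A))|` as
#' a distance-to-instability diagnostic.
#'
#' In the uncoupled limit (zero gain slope) the solution reduces to the
#' immigration-death law `var(e) = e*/N_E` (Poisson counts), which serves
#' as an exact oracle.
#'
#' @param config A [markov_config()].
#' @param fp Fixed point `c(e, i)`; computed via [markov_fixed_point()]
#'   when `NULL`.
#' @return A list of class `lna_variances`: `var_e`, `var_i`, `cov_ei`,
#'   `scaled_var_e`, `scaled_var_i`, `fp`, `A`, `B`, eigenvalues,
#'   `distance`, `stable`.
#' @export
lna_variances <- function(config, fp = NULL) {
  if (is.null(fp)) fp <- markov_fixed_point(config)
  m <- lna_matrices(config, fp)
  A <- m$A; B <- m$B
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    return(structure(list(var_e = NA_real_, var_i = NA_real_,
                          cov_ei = NA_real_, scaled_var_e = NA_real_,
                          scaled_var_i = NA_real_, fp = fp, A = A, B = B,
                          eigenvalues = ev, distance = min(abs(Re(ev))),
                          stable = FALSE),
                     class = "lna_variances"))
  # unknowns (Ve, Vi, C): rows of A S + S A' = -B
  M <- rbind(c(2 * A[1, 1], 0, 2 * A[1, 2]),
             c(0, 2 * A[2, 2], 2 * A[2, 1]),
             c(A[2, 1], A[1, 2], A[1, 1] + A[2, 2]))
  sol <- solve(M, c(-B[1, 1], -B[2, 2], 0))
  structure(list(var_e = sol[1], var_i = sol[2], cov_ei = sol[3],
                 scaled_var_e = config$N_E * sol[1],
                 scaled_var_i = config$N_I * sol[2],
                 fp = fp, A = A, B = B, eigenvalues = ev,
                 distance = min(abs(Re(ev))), stable = TRUE),
            class = "lna_variances")
}

#' Exact stochastic simulation of the birth-death model
#'
#' Gillespie simulation returning time-weighted stationary moments of the
#' intensive activities after a burn-in, plus an optionally sampled path.
#' With `constant_gain` set, the gain is frozen at that value and the
#' model reduces to two independent immigration-death processes (the
#' analytic oracle: stationary activity `G`, count variance = count mean).
#'
#' @param config A [markov_config()].
#' @param duration_ms Simulated time (ms).
#' @param burnin_ms Initial span excluded from the moments.
#' @param init Initial activities `c(e, i)`; converted to counts.
#' @param seed Integer seed (`NULL`: caller's stream).
#' @param constant_gain `NULL` (coupled gain) or a fixed rate.
#' @param max_events Safety cap on the number of transitions.
#' @param sample_n Number of equally spaced path samples (0 = none).
#' @return A list of class `markov_sim`: `mean_e`, `mean_i`, `var_e`,
#'   `var_i`, `cov_ei`, `n_events`, `t_end_ms`, and `path` (tibble).
#' @export
simulate_markov <- function(config, duration_ms, burnin_ms = 0,
                            init = c(e = 1, i = 1), seed = NULL,
                            constant_gain = NULL,
                            max_events = 5e7, sample_n = 0) {
  stopifnot(duration_ms > 0, burnin_ms >= 0, burnin_ms < duration_ms)
  gp <- config$gp; cc <- config$coupling
  gpar <- c(gp$rmax, gp$beta, gp$theta, gp$width, gp$z0)
  gain_mode <- if (is.null(constant_gain)) 1L else 0L
  if (gain_mode == 0L) gpar <- c(constant_gain, constant_gain, 0, 0, 0)
  res <- with_seed(seed, cpp_gillespie(
    config$N_E, config$N_I, config$alpha, gain_mode, gpar,
    cc[["c_EE"]], cc[["c_EI"]], cc[["c_IE"]], cc[["c_II"]],
    config$drive[["E"]], config$drive[["I"]],
    duration_ms, burnin_ms,
    as.integer(round(init[[1]] * config$N_E)),
    as.integer(round(init[[2]] * config$N_I)),
    as.integer(max_events), as.integer(sample_n)))
  out <- res[c("mean_e", "mean_i", "var_e", "var_i", "cov_ei",
               "n_events", "t_end_ms")]
  out$path <- tibble::as_tibble(res$path[c("t_ms", "e", "i")])
  class(out) <- "markov_sim"
  out
}

#' @export
print.markov_sim <- function(x, ...) {
  cat("<markov_sim> mean activities (e, i) = (",
      signif(x$mean_e, 4), ", ", signif(x$mean_i, 4),
      "); var(e) = ", signif(x$var_e, 4),
      "; events: ", x$n_events, "\n", sep = "")
  invisible(x)
}

#' Fluctuation growth on approach to criticality
#'
#' Sweeps one scalar knob of the Markov model (by default the excitatory
#' self-coupling `c_EE`) toward the instability of the linearized
#' dynamics and tabulates the LNA variances against the
#' distance-to-instability, optionally adding Gillespie estimates for a
#' subset of points.
#'
#' @param config A [markov_config()] template.
#' @param values Knob values to scan.
#' @param knob `"c_EE"` or `"drive_E"`.
#' @param simulate_ms If positive, run a Gillespie simulation of this
#'   length (with 20% burn-in) at each value.
#' @param seed Seed for the simulated points.
#' @return Tibble with the knob value, `distance`, `scaled_var_e`,
#'   `scaled_var_i`, `stable`, and (if simulated) `sim_var_e`.
#' @export
variance_vs_criticality <- function(config, values, knob = c("c_EE", "drive_E"),
                                    simulate_ms = 0, seed = 1) {
  knob <- match.arg(knob)
  purrr::map_dfr(seq_along(values), function(j) {
    v <- values[j]
    cf <- config
    if (knob == "c_EE") cf$coupling[["c_EE"]] <- v else cf$drive[["E"]] <- v
    ln <- tryCatch(lna_variances(cf), error = function(e) NULL)
    row <- tibble::tibble(value = v,
                          distance = if (is.null(ln)) NA_real_ else ln$distance,
                          scaled_var_e = if (is.null(ln)) NA_real_ else ln$scaled_var_e,
                          scaled_var_i = if (is.null(ln)) NA_real_ else ln$scaled_var_i,
                          stable = !is.null(ln) && isTRUE(ln$stable))
    if (simulate_ms > 0) {
      fp <- if (!is.null(ln)) ln$fp else c(e = 1, i = 1)
      sim <- simulate_markov(cf, simulate_ms, burnin_ms = 0.2 * simulate_ms,
                             init = fp, seed = derive_seed(seed, paste0("vc", j)))
      row$sim_var_e <- sim$var_e * cf$N_E
    }
    row
  })
}
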