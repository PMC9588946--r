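#' Smooth threshold-linear gain with soft saturation
#'
#' Population transfer function mapping net synaptic input (current units,
#' leak-conductance-normalized mV) to an output rate in Hz: zero below
#' threshold, linear mid-section of slope `beta`, saturating at `rmax`;
#' corners rounded by softplus smoothing of width `width`, and a small
#' offset `z0` subtracted so that the function is exactly zero below
#' threshold (making the quiescent state a true fixed point). The default
#' shape parameters are frozen from a one-off calibration against the
#' firing of uncoupled LIF neurons under Poisson drive (see
#' [calibrate_gain()]).
#'
#' @param rmax Maximal rate (Hz).
#' @param beta Linear-section slope (Hz per input unit).
#' @param theta Threshold input level.
#' @param width Smoothing width (Hz).
#' @param z0 Offset (Hz) subtracted before clipping at zero.
#' @return A list of class `gain_params`.
#' @export
gain_params <- function(rmax = 500, beta = eicrit_gain_default$beta,
                        theta = eicrit_gain_default$theta,
                        width = eicrit_gain_default$width, z0 = 0.1) {
  stopifnot(rmax > 0, beta > 0, width > 0)
  structure(list(rmax = rmax, beta = beta, theta = theta, width = width,
                 z0 = z0), class = "gain_params")
}

# frozen single-neuron transfer-curve fit (calibrate_gain with the default
# neuron parameters and calibrated conductance scale)
eicrit_gain_default <- list(beta = 22.21515, theta = 25.65327,
                            width = 128.6294)

#' @rdname gain_params
#' @param z Net input (vectorized).
#' @param gp A `gain_params` object.
#' @return For `gain()`: output rate(s), Hz.
#' @export
gain <- function(z, gp = gain_params()) {
  sp <- function(x, w) ifelse(x / w > 30, x, w * log1p(exp(pmin(x / w, 30))))
  inner <- sp(gp$beta * (z - gp$theta), gp$width)
  pmax(0, gp$rmax - sp(gp$rmax - inner, gp$width) - gp$z0)
}

#' Two-population rate-model parameters
#'
#' Mean-field description of the E-I network: population rates `rho_E`,
#' `rho_I` (Hz) obey
#' \deqn{\tau_m \dot\rho_x = -\rho_x + G(z_x),\qquad
#'   z_x = c_{xE}\rho_E + c_{xI}\rho_I + c_{ext}w_{ext}\rho_{ext,x}}
#' with coupling coefficients
#' `c_xy = tau_syn * g0_y * k_xy * w_xy * (V_R_y - <V_x>)` and the mean
#' potential `<V_x>` given by the conductance-weighted average of the
#' reversal potentials (fluctuation-driven regime). Constructed either
#' directly or from a spiking [network_config()] so both layers share one
#' parameter set.
#'
#' @param k Named in-degrees `c(EE=,EI=,IE=,II=)`.
#' @param w Named mean weights `c(EE=,EI=,IE=,II=)`.
#' @param rho_ext_E,rho_ext_I External rates (Hz).
#' @param w_ext External-synapse weight.
#' @param params A [neuron_params()].
#' @param gp A [gain_params()].
#' @return A list of class `meanfield_params`.
#' @export
meanfield_params <- function(k, w, rho_ext_E, rho_ext_I = 150, w_ext = 0.54,
                             params = neuron_params(), gp = gain_params()) {
  structure(list(k = k[c("EE", "EI", "IE", "II")],
                 w = w[c("EE", "EI", "IE", "II")],
                 rho_ext_E = rho_ext_E, rho_ext_I = rho_ext_I, w_ext = w_ext,
                 params = params, gp = gp),
            class = "meanfield_params")
}

#' @rdname meanfield_params
#' @param config A [network_config()].
#' @param drive A [drive_params()].
#' @export
meanfield_from_network <- function(config, drive, params = neuron_params(),
                                   gp = gain_params()) {
  k <- config$k; names(k) <- sub("^k_", "", names(k))
  meanfield_params(k, config$w_mean, drive$rho_ext_E, drive$rho_ext_I,
                   drive$w_ext, params, gp)
}

# per-population synaptic conductances at rates rho (Hz); tau in seconds
mf_conductances <- function(mf, rho_E, rho_I, population) {
  p <- mf$params
  tse <- p$tau_syn_exc * 1e-3; tsi <- p$tau_syn_inh * 1e-3
  if (population == "E") {
    ge <- tse * p$g0_exc * (mf$k[["EE"]] * mf$w[["EE"]] * rho_E +
                              mf$w_ext * mf$rho_ext_E)
    gi <- tsi * p$g0_inh * mf$k[["EI"]] * mf$w[["EI"]] * rho_I
  } else {
    ge <- tse * p$g0_exc * (mf$k[["IE"]] * mf$w[["IE"]] * rho_E +
                              mf$w_ext * mf$rho_ext_I)
    gi <- tsi * p$g0_inh * mf$k[["II"]] * mf$w[["II"]] * rho_I
  }
  list(ge = ge, gi = gi)
}

#' Mean membrane potential of a population at given rates
#'
#' Conductance-weighted average of the leak and synaptic reversal
#' potentials (the steady state of the voltage equation under
#' time-averaged conductances), including the external-drive contribution
#' on the excitatory channel.
#'
#' @param rho_E,rho_I Population rates (Hz); vectorized.
#' @param mf A [meanfield_params()].
#' @param population `"E"` or `"I"`.
#' @return Mean potential (mV).
#' @export
average_potential <- function(rho_E, rho_I, mf, population = c("E", "I")) {
  population <- match.arg(population)
  stopifnot(all(rho_E >= 0), all(rho_I >= 0))
  p <- mf$params
  g <- mf_conductances(mf, rho_E, rho_I, population)
  (p$g_leak * p$v_leak + g$ge * p$V_R_exc + g$gi * p$V_R_inh) /
    (p$g_leak + g$ge + g$gi)
}

#' Coupling coefficients of the linearized rate model
#'
#' `c_xy = tau_syn * g0_y * k_xy * w_xy * (V_R_y - <V_x>)` evaluated at
#' the operating rates (the mean potentials are rate-dependent). The
#' inhibitory coefficients `c_EI`, `c_II` are negative since the
#' inhibitory reversal potential lies below the mean potential.
#'
#' @param mf A [meanfield_params()].
#' @param rho Named rates `c(E=,I=)` (Hz) at which to evaluate.
#' @return Named numeric `c(c_EE, c_EI, c_IE, c_II)`.
#' @export
coupling_coefficients <- function(mf, rho = c(E = 5, I = 10)) {
  p <- mf$params
  tse <- p$tau_syn_exc * 1e-3; tsi <- p$tau_syn_inh * 1e-3
  vE <- average_potential(rho[["E"]], rho[["I"]], mf, "E")
  vI <- average_potential(rho[["E"]], rho[["I"]], mf, "I")
  c(c_EE = tse * p$g0_exc * mf$k[["EE"]] * mf$w[["EE"]] * (p$V_R_exc - vE),
    c_EI = tsi * p$g0_inh * mf$k[["EI"]] * mf$w[["EI"]] * (p$V_R_inh - vE),
    c_IE = tse * p$g0_exc * mf$k[["IE"]] * mf$w[["IE"]] * (p$V_R_exc - vI),
    c_II = tsi * p$g0_inh * mf$k[["II"]] * mf$w[["II"]] * (p$V_R_inh - vI))
}

# net input to the gain of each population at rates (rho_E, rho_I)
mf_input <- function(mf, rho_E, rho_I) {
  p <- mf$params
  vE <- average_potential(rho_E, rho_I, mf, "E")
  vI <- average_potential(rho_E, rho_I, mf, "I")
  gE <- mf_conductances(mf, rho_E, rho_I, "E")
  gI <- mf_conductances(mf, rho_E, rho_I, "I")
  list(zE = gE$ge * (p$V_R_exc - vE) + gE$gi * (p$V_R_inh - vE),
       zI = gI$ge * (p$V_R_exc - vI) + gI$gi * (p$V_R_inh - vI))
}

#' Rate-dynamics right-hand side
#'
#' `d rho_x / dt = -(rho_x - G(z_x)) / tau_m`, per ms.
#'
#' @param rho Numeric `c(rho_E, rho_I)` (Hz).
#' @param mf A [meanfield_params()].
#' @return Numeric derivative vector (Hz per ms).
#' @export
rate_ode_rhs <- function(rho, mf) {
  stopifnot(all(rho >= 0))
  z <- mf_input(mf, rho[[1]], rho[[2]])
  c(-(rho[[1]] - gain(z$zE, mf$gp)) / mf$params$tau_m,
    -(rho[[2]] - gain(z$zI, mf$gp)) / mf$params$tau_m)
}

#' Integrate the rate model
#'
#' @inheritParams rate_ode_rhs
#' @param rho0 Initial rates (Hz).
#' @param t_max Horizon (ms).
#' @param dt Output sampling step (ms).
#' @return Tibble `t_ms`, `rho_E`, `rho_I`.
#' @export
integrate_rate_ode <- function(mf, rho0 = c(1, 1), t_max = 2000, dt = 1) {
  f <- function(t, y, parms) list(rate_ode_rhs(pmax(y, 0), mf))
  out <- deSolve::ode(y = pmax(rho0, 0), times = seq(0, t_max, by = dt),
                      func = f, parms = NULL, method = "lsoda")
  tibble::tibble(t_ms = out[, 1], rho_E = pmax(out[, 2], 0),
                 rho_I = pmax(out[, 3], 0))
}

mf_residual <- function(mf, rho_E, rho_I) {
  z <- mf_input(mf, rho_E, rho_I)
  list(FE = gain(z$zE, mf$gp) - rho_E, FI = gain(z$zI, mf$gp) - rho_I)
}

mf_jacobian <- function(mf, rho, h = 1e-4) {
  # Jacobian of the rate dynamics (per ms) by central differences
  f <- function(r) rate_ode_rhs(pmax(r, 0), mf)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    rp <- rho; rm <- rho
    hj <- max(h, h * abs(rho[j]))
    rp[j] <- rho[j] + hj; rm[j] <- max(rho[j] - hj, 0)
    J[, j] <- (f(rp) - f(rm)) / (rp[j] - rm[j])
  }
  J
}

classify_fp <- function(tr, dt_) {
  if (dt_ < 0) "saddle"
  else if (tr < 0 && tr^2 >= 4 * dt_) "stable node"
  else if (tr < 0) "stable focus"
  else if (tr^2 >= 4 * dt_) "unstable node"
  else "unstable focus"
}

regime_label <- function(mf, rho_E, rho_I) {
  gp <- mf$gp
  if (rho_E <= 1 && rho_I <= 1) return("Q")
  if (rho_E >= 0.5 * gp$rmax) return("H")
  # local slope of the gain: linear-section points sit near the full slope
  z <- mf_input(mf, rho_E, rho_I)$zE
  sl <- (gain(z + 0.05, gp) - gain(z - 0.05, gp)) / 0.1
  if (sl > 0.5 * gp$beta) "M" else "L"
}

#' Fixed points of the rate model
#'
#' All solutions of `rho_x = G(z_x(rho))` inside the box
#' `[0, 1.2 rmax]^2`, located by sign-change bracketing on a dense grid
#' (plus explicit boundary checks for the quiescent/axis states) and
#' refined by damped Newton iteration; duplicates merged within 1e-3 Hz.
#' Each point carries its Jacobian trace/determinant, a stability
#' classification, and a regime label: `Q` quiescent, `L` low-rate, `M`
#' linear-section, `H` high-rate.
#'
#' @param mf A [meanfield_params()].
#' @param n_grid Bracketing grid resolution per axis.
#' @return Tibble of class `mf_fixed_points`: `rho_E`, `rho_I`, `trace`,
#'   `det`, `classification`, `regime`, `residual`.
#' @export
find_fixed_points <- function(mf, n_grid = 200) {
  rmax <- mf$gp$rmax
  hi <- 1.2 * rmax
  gr <- seq(0, hi, length.out = n_grid)
  FE <- outer(gr, gr, function(a, b) mf_residual(mf, a, b)$FE)
  FI <- outer(gr, gr, function(a, b) mf_residual(mf, a, b)$FI)
  cand <- list()
  sgn_change <- function(M, i, j) {
    v <- c(M[i, j], M[i + 1, j], M[i, j + 1], M[i + 1, j + 1])
    any(v <= 0) && any(v >= 0)
  }
  for (i in seq_len(n_grid - 1)) for (j in seq_len(n_grid - 1)) {
    if (sgn_change(FE, i, j) && sgn_change(FI, i, j))
      cand[[length(cand) + 1]] <- c(mean(gr[i:(i + 1)]), mean(gr[j:(j + 1)]))
  }
  # boundary states: origin and single-population states on the axes
  r0 <- mf_residual(mf, 0, 0)
  if (abs(r0$FE) < 1e-9 && abs(r0$FI) < 1e-9) cand <- c(cand, list(c(0, 0)))
  fE0 <- function(ri) mf_residual(mf, 0, ri)$FI
  fI0 <- function(re) mf_residual(mf, re, 0)$FE
  for (i in seq_len(n_grid - 1)) {
    if (abs(mf_residual(mf, 0, gr[i])$FE) < 1e-9 &&
        fE0(gr[i]) * fE0(gr[i + 1]) <= 0 && fE0(gr[i]) != 0) {
      ri <- uniroot(fE0, gr[i:(i + 1)])$root
      cand <- c(cand, list(c(0, ri)))
    }
    if (abs(mf_residual(mf, gr[i], 0)$FI) < 1e-9 &&
        fI0(gr[i]) * fI0(gr[i + 1]) <= 0 && fI0(gr[i]) != 0) {
      re <- uniroot(fI0, gr[i:(i + 1)])$root
      cand <- c(cand, list(c(re, 0)))
    }
  }
  refine <- function(x0) {
    x <- pmax(x0, 0)
    for (it in 1:60) {
      r <- mf_residual(mf, x[1], x[2])
      Fv <- c(r$FE, r$FI)
      if (max(abs(Fv)) < 1e-10) break
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- max(1e-6, 1e-6 * abs(x[j]))
        xp <- x; xp[j] <- x[j] + h
        rp <- mf_residual(mf, xp[1], xp[2])
        J[, j] <- (c(rp$FE, rp$FI) - Fv) / h
      }
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      step <- pmin(pmax(step, -rmax / 4), rmax / 4)
      x <- pmax(x - step, 0)
    }
    r <- mf_residual(mf, x[1], x[2])
    if (max(abs(c(r$FE, r$FI))) > 1e-6) return(NULL)
    x
  }
  roots <- purrr::compact(purrr::map(cand, refine))
  if (!length(roots))
    return(structure(tibble::tibble(rho_E = numeric(), rho_I = numeric(),
                                    trace = numeric(), det = numeric(),
                                    classification = character(),
                                    regime = character(),
                                    residual = numeric()),
                     class = c("mf_fixed_points", class(tibble::tibble()))))
  pts <- do.call(rbind, roots)
  # deduplicate by coarse position but keep the polished coordinates
  pts <- pts[!duplicated(round(pts / 1e-3)), , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(pts)), function(i) {
    rho <- pmax(pts[i, ], 0)
    J <- mf_jacobian(mf, rho)
    tr <- J[1, 1] + J[2, 2]; de <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    r <- mf_residual(mf, rho[1], rho[2])
    tibble::tibble(rho_E = rho[1], rho_I = rho[2], trace = tr, det = de,
                   classification = classify_fp(tr, de),
                   regime = regime_label(mf, rho[1], rho[2]),
                   residual = max(abs(c(r$FE, r$FI))))
  })
  out <- dplyr::distinct(dplyr::bind_rows(rows), .data$rho_E, .data$rho_I,
                         .keep_all = TRUE)
  structure(out, class = c("mf_fixed_points", class(out)))
}

#' Nullclines of the rate model
#'
#' Solution branches of the two scalar fixed-point equations,
#' parameterized by `rho_E` (gain monotonicity makes each single-valued in
#' this parameterization), plus the linearized-nullcline slopes
#' `-c_EE/c_EI` (excitatory) and `-c_IE/c_II` (inhibitory) evaluated at
#' the reference rates.
#'
#' @param mf A [meanfield_params()].
#' @param rho_E_grid Grid of excitatory rates (Hz).
#' @param slopes_at Rates at which the linearized slopes are evaluated.
#' @return Tibble `rho_E`, `rho_I_exc_nullcline`, `rho_I_inh_nullcline`
#'   with slope attributes `slope_exc`, `slope_inh`.
#' @export
nullclines <- function(mf, rho_E_grid = seq(0, 100, length.out = 201),
                       slopes_at = c(E = 5, I = 10)) {
  stopifnot(all(rho_E_grid >= 0))
  hi <- 1.2 * mf$gp$rmax
  solve_branch <- function(re, which) {
    f <- function(ri) {
      r <- mf_residual(mf, re, ri)
      if (which == "E") r$FE else r$FI
    }
    lo <- f(0); up <- f(hi)
    if (is.na(lo) || is.na(up) || lo * up > 0) {
      if (abs(lo) < 1e-9) return(0)
      return(NA_real_)
    }
    uniroot(f, c(0, hi), tol = 1e-9)$root
  }
  riE <- vapply(rho_E_grid, solve_branch, numeric(1), which = "E")
  riI <- vapply(rho_E_grid, solve_branch, numeric(1), which = "I")
  cc <- coupling_coefficients(mf, slopes_at)
  out <- tibble::tibble(rho_E = rho_E_grid,
                        rho_I_exc_nullcline = riE,
                        rho_I_inh_nullcline = riI)
  attr(out, "slope_exc") <- -cc[["c_EE"]] / cc[["c_EI"]]
  attr(out, "slope_inh") <- -cc[["c_IE"]] / cc[["c_II"]]
  out
}

#' Threshold-drive constant of the linearized nullclines
#'
#' `d = g_L (v_rest - v_th) / (tau_syn * g0_exc * (v_th - V_R_exc))` in
#' Hz: the unit-weight external rate whose mean current depolarizes a
#' neuron from rest to threshold.
#'
#' @param params A [neuron_params()].
#' @export
d_constant <- function(params = neuron_params()) {
  params$g_leak * (params$v_rest - params$v_th) /
    (params$tau_syn_exc * 1e-3 * params$g0_exc * (params$v_th - params$V_R_exc))
}

#' Bogdanov-Takens matching residuals
#'
#' Near the BT point the slopes and intercepts of the linearized
#' nullclines match: the slope residual is `c_EE c_II - c_EI c_IE`, the
#' intercept residual is
#' `rho*_ext,E - [c_EE/c_IE (rho*_ext,I - d) + d]` with external rates in
#' unit-weight equivalents (`w_ext * rho_ext`), and
#' `deltaW = W_EE_eff * W_II - W_EI * W_IE` tracks the same balance at the
#' weight level (using the STP-discounted effective E-to-E weight when an
#' efficacy is supplied).
#'
#' @param mf A [meanfield_params()].
#' @param rho Rates at which coefficients are evaluated.
#' @param u_eff Mean synaptic efficacy discounting `w_EE` (1 = no STP).
#' @return A list of class `bt_residuals`: `slope_residual`,
#'   `intercept_residual`, `deltaW`, plus the coefficients used.
#' @export
bt_residuals <- function(mf, rho = c(E = 5, I = 10), u_eff = 1) {
  cc <- coupling_coefficients(mf, rho)
  ccEE_eff <- cc[["c_EE"]] * u_eff
  d <- d_constant(mf$params)
  slope_res <- ccEE_eff * cc[["c_II"]] - cc[["c_EI"]] * cc[["c_IE"]]
  rExtE <- mf$w_ext * mf$rho_ext_E
  rExtI <- mf$w_ext * mf$rho_ext_I
  int_res <- rExtE - (ccEE_eff / cc[["c_IE"]] * (rExtI - d) + d)
  dW <- (u_eff * mf$w[["EE"]]) * mf$w[["II"]] - mf$w[["EI"]] * mf$w[["IE"]]
  structure(list(slope_residual = unname(slope_res),
                 intercept_residual = unname(int_res),
                 deltaW = unname(dW), coefficients = cc, d = d),
            class = "bt_residuals")
}

#' Slow-fast dynamics with short-term depression
#'
#' Fast rate dynamics with an effective E-to-E weight, coupled to the slow
#' depression of that weight. In fast time `t_f = t / tau_m`:
#' \deqn{\dot\rho = -(\rho - G(z(\rho; w_{EE}))),\qquad
#'   \dot w_{EE} = \mu (w^0_{EE} - w_{EE}) - q\,\tau_m\,w_{EE}\,\rho_E}
#' with `mu = tau_m / tau_STP` (time-scale separation requires `mu` small).
#'
#' @param rho Rates `c(E, I)` (Hz).
#' @param w_EE Current effective E-to-E mean weight.
#' @param mf A [meanfield_params()] (its `w[["EE"]]` is overridden by
#'   `w_EE`).
#' @param stp An [stp_params()].
#' @return Numeric `c(drho_E, drho_I, dw_EE)` in fast-time units.
#' @export
slow_fast_rhs <- function(rho, w_EE, mf, stp) {
  mu <- mf$params$tau_m / stp$tau_STP
  mf2 <- mf; mf2$w[["EE"]] <- w_EE
  z <- mf_input(mf2, rho[[1]], rho[[2]])
  c(-(rho[[1]] - gain(z$zE, mf$gp)),
    -(rho[[2]] - gain(z$zI, mf$gp)),
    mu * (stp$w0_EE - w_EE) - stp$q * mf$params$tau_m * 1e-3 * w_EE * rho[[1]])
}

#' Stationary effective weight under depression
#'
#' `w_EE_st = w0 / (1 + tau_STP * q * rho_E)`.
#'
#' @param rho_E Excitatory rate (Hz).
#' @param stp An [stp_params()].
#' @export
stationary_wEE <- function(rho_E, stp) {
  stp$w0_EE / (1 + stp$tau_STP * 1e-3 * stp$q * rho_E)
}

#' Necessary conditions for up-to-down state transitions
#'
#' In the bistable configuration, switching from the high (up) state
#' requires (i) a stable high fixed point at full resources,
#' `k_EE w0 > k_EI w_EI`, and (ii) that the depressed stationary weight at
#' the high-state rate is no longer sufficient,
#' `k_EE w0 / (1 + tau_STP q rho_H) < k_EI w_EI`.
#'
#' @param k Named in-degrees (`EE`, `EI` used).
#' @param w0_EE Baseline E-to-E weight.
#' @param w_EI E-from-I weight.
#' @param stp An [stp_params()].
#' @param rho_H High-state excitatory rate (Hz).
#' @return Named logical `c(high_state, depression_escape)`.
#' @export
up_down_conditions <- function(k, w0_EE, w_EI, stp, rho_H) {
  lhs <- k[["EE"]] * w0_EE
  rhs <- k[["EI"]] * w_EI
  c(high_state = unname(lhs > rhs),
    depression_escape =
      unname(lhs / (1 + stp$tau_STP * 1e-3 * stp$q * rho_H) < rhs))
}

#' Regime-label grid over control parameters
#'
#' Labels each `(w_EE, rho_ext_E)` cell with the sorted multiset of
#' fixed-point regime labels (e.g. `"Q"`, `"Q+L+M"`), mirroring the local
#' bifurcation diagram in the two control parameters.
#'
#' @param mf A [meanfield_params()] template.
#' @param w_EE_values,rho_ext_values Grid values.
#' @param n_grid Root-bracketing resolution passed to
#'   [find_fixed_points()].
#' @return Tibble `w_EE`, `rho_ext_E`, `label`, `n_fixed_points`.
#' @export
scan_bifurcation <- function(mf, w_EE_values, rho_ext_values, n_grid = 120) {
  grid <- tidyr::expand_grid(w_EE = w_EE_values, rho_ext_E = rho_ext_values)
  res <- purrr::pmap(grid, function(w_EE, rho_ext_E) {
    mf2 <- mf; mf2$w[["EE"]] <- w_EE; mf2$rho_ext_E <- rho_ext_E
    fp <- find_fixed_points(mf2, n_grid = n_grid)
    tibble::tibble(label = paste(sort(fp$regime), collapse = "+"),
                   n_fixed_points = nrow(fp))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Calibrate the gain function against single-neuron firing
#'
#' Simulates uncoupled LIF neurons under a range of Poisson drive rates,
#' converts each rate to the net input `z` seen by the rate model, and
#' fits the threshold-linear-soft shape (`beta`, `theta`, `width`) by
#' least squares with `rmax` held fixed. The package's default
#' [gain_params()] were frozen from one such run; this function documents
#' and reproduces the procedure.
#'
#' @param params A [neuron_params()].
#' @param w_ext Drive weight used in the calibration runs.
#' @param rates Drive-rate grid (Hz).
#' @param n_neurons Independent neurons per rate.
#' @param duration_ms Simulated time per rate.
#' @param seed RNG seed.
#' @param rmax Fixed maximal rate.
#' @return List with the fitted `gain_params`, and the measured transfer
#'   tibble (`rate_ext`, `z`, `rate_out`).
#' @export
calibrate_gain <- function(params = neuron_params(), w_ext = 0.54,
                           rates = c(seq(100, 1400, by = 100),
                                     seq(1600, 4000, by = 300)),
                           n_neurons = 150, duration_ms = 3000, seed = 1,
                           rmax = 500) {
  cfg <- network_config(n_exc = n_neurons, n_inh = 0, k_EE = 0, k_EI = 0,
                        k_IE = 0, k_II = 0, seed = seed)
  syn <- build_network(cfg)
  mf0 <- meanfield_params(k = c(EE = 0, EI = 0, IE = 0, II = 0),
                          w = c(EE = 1, EI = 1, IE = 1, II = 1),
                          rho_ext_E = 0, w_ext = w_ext, params = params)
  meas <- purrr::map_dfr(seq_along(rates), function(i) {
    r <- rates[i]
    sim <- simulate_network(syn, drive_params(r, 0, w_ext), duration_ms,
                            seed = derive_seed(seed, paste0("gain", i)),
                            params = params, n_exc = n_neurons, n_inh = 0,
                            sample_every_ms = duration_ms)
    mf0$rho_ext_E <- r
    z <- mf_input(mf0, 0, 0)$zE
    tibble::tibble(rate_ext = r, z = z,
                   rate_out = nrow(sim$spikes) / (n_neurons * duration_ms * 1e-3))
  })
  fit <- optim(c(beta = 30, theta = 10, width = 20), function(p) {
    if (any(p <= 0)) return(1e12)
    gp <- gain_params(rmax = rmax, beta = p[1], theta = p[2], width = p[3])
    sum((gain(meas$z, gp) - meas$rate_out)^2)
  }, method = "Nelder-Mead", control = list(maxit = 2000))
  list(gp = gain_params(rmax = rmax, beta = fit$par[1], theta = fit$par[2],
                        width = fit$par[3]),
       transfer = meas, objective = fit$value)
}
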