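#' Directed-percolation Langevin field configuration
#'
#' Spatially extended activity field `E(x, t) >= 0` on a periodic 1D ring
#' (`ny = 1`) or 2D lattice, obeying
#' \deqn{\partial_t E = \gamma E - u E^2 + D \Delta E + h + \sqrt{2\sigma^2 E / N} \,\xi}
#' with multiplicative square-root (demographic) noise. Integration is by
#' operator splitting: the nonlinear, diffusion and drive terms advance by
#' explicit Euler, and the linear-plus-noise part is propagated exactly by
#' Poisson-Gamma sampling of its transition law, so the absorbing state
#' `E = 0` is reached exactly (naive Euler-Maruyama with clipping
#' rectifies the noise and never extinguishes). Negative deterministic
#' increments are clipped at zero and counted. This is the
#' directed-percolation universality class: at
#' `gamma = 0` and `h = 0` the absorbing state `E = 0` is marginal and
#' point-seeded excursions form scale-free avalanches.
#'
#' @param nx,ny Lattice extent (sites).
#' @param dx Lattice spacing.
#' @param dt Time step; must satisfy the explicit-diffusion stability
#'   bound `D * dt / dx^2 <= 1/4` (1/2 would do in 1D; the stricter bound
#'   is enforced uniformly).
#' @param D Diffusion constant.
#' @param gamma Linear growth rate (distance to the critical point).
#' @param u_quad Quadratic saturation coefficient.
#' @param sigma2 Noise variance scale.
#' @param N_local Local system size (noise is demographic, variance
#'   `2 sigma2 E / N_local` per unit length).
#' @param drive Homogeneous external input `h`.
#' @return A list of class `field_config`.
#' @export
field_config <- function(nx, ny = 1, dx = 1, dt = 0.1, D = 1,
                         gamma = 0, u_quad = 1, sigma2 = 1, N_local = 100,
                         drive = 0) {
  stopifnot(nx >= 3, ny >= 1, dx > 0, dt > 0, D >= 0, u_quad >= 0,
            sigma2 >= 0, N_local > 0, drive >= 0)
  if (D > 0 && D * dt / dx^2 > 0.25)
    abort("stability violation: require D * dt / dx^2 <= 1/4")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dt = dt,
                 D = D, gamma = gamma, u_quad = u_quad, sigma2 = sigma2,
                 N_local = N_local, drive = drive),
            class = "field_config")
}

#' Integrate the directed-percolation field
#'
#' @param config A [field_config()].
#' @param E0 Initial field (length `nx * ny`, row-major by `ny`); a scalar
#'   is recycled.
#' @param duration Total integration time (field time units).
#' @param sample_every Record the spatial mean every this many steps
#'   (0 = no series).
#' @param seed Integer seed (`NULL`: caller's stream).
#' @param stop_when_absorbed Stop as soon as total activity falls below
#'   `eps` (only without drive).
#' @param eps Absorption threshold on `sum(E) * dx`.
#' @return A list of class `dp_field_sim`: final `E` (matrix `nx` x
#'   `ny`), `steps`, `size_integral` (space-time integral of activity),
#'   `truncations`, `absorbed`, and `series` (tibble `t`, `E_mean`).
#' @export
simulate_dp_field <- function(config, E0 = 0, duration,
                              sample_every = 0, seed = NULL,
                              stop_when_absorbed = FALSE, eps = 1e-12) {
  ns <- config$nx * config$ny
  E0 <- rep_len(as.numeric(E0), ns)
  stopifnot(all(E0 >= 0), duration > 0)
  n_steps <- ceiling(duration / config$dt)
  res <- with_seed(seed, cpp_dp_field(
    E0, config$nx, config$ny, config$dt, config$dx, config$D,
    config$gamma, config$u_quad, config$sigma2, config$N_local,
    config$drive, n_steps, as.integer(sample_every),
    stop_when_absorbed, eps,
    FALSE, numeric(0), 0, 0, 0, 1, 1))
  structure(list(E = matrix(res$E, config$nx, config$ny),
                 steps = res$steps, size_integral = res$size_integral,
                 truncations = res$truncations,
                 absorbed = res$steps < n_steps,
                 series = tibble::tibble(t = res$series$t_ms,
                                         E_mean = res$series$E_mean),
                 config = config),
            class = "dp_field_sim")
}

#' Point-seeded avalanches of the critical field
#'
#' Repeatedly seeds a single site of an otherwise empty 1D ring with
#' activity `seed_value` and integrates without drive until absorption
#' (or `max_steps`). Avalanche size is the space-time integral of the
#' activity, duration the time to absorption. At `gamma = 0` sizes follow
#' the mean-field directed-percolation power law (exponent 3/2).
#'
#' @param config A 1D [field_config()] (requires `ny = 1`,
#'   `drive = 0`).
#' @param n_avalanches Number of independent runs.
#' @param seed_value Initial activity of the seeded site.
#' @param max_steps Cap per run; runs hitting it are flagged truncated.
#' @param seed Integer seed.
#' @return Tibble `size`, `duration`, `truncated`.
#' @export
dp_avalanches <- function(config, n_avalanches, seed_value = 1,
                          max_steps = 1e6, seed = NULL) {
  stopifnot(config$ny == 1, config$drive == 0, n_avalanches >= 1)
  res <- with_seed(seed, cpp_dp_avalanches(
    config$nx, config$dt, config$dx, config$D, config$gamma,
    config$u_quad, config$sigma2, config$N_local, seed_value, 1e-12,
    as.integer(max_steps), as.integer(n_avalanches)))
  tibble::tibble(size = res$size, duration = res$duration,
                 truncated = as.logical(res$truncated))
}

#' Rescale field parameters to the standard DP normal form
#'
#' Substituting `E = a * E'` with `a = sigma / sqrt(u_quad * N_local)`
#' brings the Langevin field to the form in which the quadratic and noise
#' coefficients coincide: `gamma' = gamma`, `D' = D`,
#' `u' = sigma * sqrt(u_quad / N_local)` multiplies both the `E'^2` drift
#' term and the `sqrt(E')` noise amplitude. Only `gamma` then measures the
#' distance to criticality.
#'
#' @param config A [field_config()].
#' @return List `a` (field rescaling), `gamma`, `D`, `u`, and a
#'   `field_config` `config` realizing the normal form
#'   (`u_quad = u`, `sigma2 = u * N_local / 2`... i.e. noise variance
#'   `2 sigma2 / N_local = 2u`).
#' @export
rescale_to_dp <- function(config) {
  stopifnot(config$u_quad > 0, config$sigma2 > 0)
  sig <- sqrt(config$sigma2)
  a <- sig / sqrt(config$u_quad * config$N_local)
  u <- sig * sqrt(config$u_quad / config$N_local)
  cfg <- config
  cfg$u_quad <- u
  cfg$sigma2 <- u
  cfg$N_local <- 1
  list(a = a, gamma = config$gamma, D = config$D, u = u, config = cfg)
}

#' Activity field coupled to slow synaptic depression
#'
#' Field extension of the slow-fast rate dynamics: the activity `E` and a
#' resource/efficacy field `Omega` obey
#' \deqn{\tau_m \partial_t E = (-\alpha + \Omega) E - u E^2 + D \Delta E + \psi,}
#' \deqn{\partial_t \Omega = (\Omega_0 - \Omega)/\tau_{STP} - q\, \Omega\, E,}
#' with the same demographic noise `psi` as the plain DP field. Activity
#' bursts deplete `Omega` locally; recovery on the slow time scale
#' `tau_STP` self-organizes the linear coefficient `-alpha + Omega`
#' around zero, i.e. around the DP critical point.
#'
#' @param Omega0 Resting value of the depression field (take
#'   `Omega0 > alpha_decay` so the quiescent state is unstable at full
#'   resources).
#' @param alpha_decay Linear activity decay rate.
#' @param q Depletion fraction per unit activity.
#' @param tau_STP Recovery time constant (ms).
#' @param tau_m Membrane (fast) time constant (ms).
#' @return A list of class `stp_field_params`.
#' @export
stp_field_params <- function(Omega0 = 1.2, alpha_decay = 1, q = 0.3,
                             tau_STP = 50, tau_m = 20) {
  stopifnot(Omega0 > 0, alpha_decay > 0, q >= 0, tau_STP > 0, tau_m > 0)
  structure(list(Omega0 = Omega0, alpha_decay = alpha_decay, q = q,
                 tau_STP = tau_STP, tau_m = tau_m),
            class = "stp_field_params")
}

#' @rdname stp_field_params
#' @param config A [field_config()] (`gamma` is ignored; the linear
#'   coefficient is `-alpha + Omega`). `dt` is in ms here.
#' @param sfp An `stp_field_params` object.
#' @param E0,Omega0_field Initial fields (scalars recycled; `Omega`
#'   defaults to `Omega0`).
#' @param duration_ms Total time (ms).
#' @param sample_every Series sampling stride (steps).
#' @param seed Integer seed.
#' @return For `simulate_stp_field()`: list of class `stp_field_sim` with
#'   final `E` and `Omega` matrices, the spatial-mean `series` (tibble
#'   `t_ms`, `E_mean`, `Omega_mean`), `truncations`, and the inputs.
#' @export
simulate_stp_field <- function(config, sfp, E0 = 0.1, Omega0_field = NULL,
                               duration_ms, sample_every = 10, seed = NULL) {
  ns <- config$nx * config$ny
  E0 <- rep_len(as.numeric(E0), ns)
  Om0 <- rep_len(as.numeric(Omega0_field %||% sfp$Omega0), ns)
  stopifnot(all(E0 >= 0), duration_ms > 0)
  n_steps <- ceiling(duration_ms / config$dt)
  res <- with_seed(seed, cpp_dp_field(
    E0, config$nx, config$ny, config$dt, config$dx, config$D,
    0, config$u_quad, config$sigma2, config$N_local,
    config$drive, n_steps, as.integer(sample_every),
    FALSE, 1e-12,
    TRUE, Om0, sfp$Omega0, sfp$alpha_decay, sfp$q, sfp$tau_STP, sfp$tau_m))
  structure(list(E = matrix(res$E, config$nx, config$ny),
                 Omega = matrix(res$Omega, config$nx, config$ny),
                 steps = res$steps, truncations = res$truncations,
                 series = tibble::tibble(t_ms = res$series$t_ms,
                                         E_mean = res$series$E_mean,
                                         Omega_mean = res$series$Omega_mean),
                 config = config, sfp = sfp),
            class = "stp_field_sim")
}

#' Homogeneous stationary state of the depression-coupled field
#'
#' Intersection of the stationary activity branch `E = (-alpha +
#' Omega)/u` with the stationary depression branch `Omega = Omega_0 / (1 +
#' q tau_STP E)` (noise-free, homogeneous): the positive root of
#' `u q tau E^2 + (u + alpha q tau) E + (alpha - Omega_0) = 0` (with
#' `tau = tau_STP` in the time units of `q E`, i.e. seconds when `E` is in
#' Hz; here `E` and the rates share one unit system, so `tau_STP` enters
#' in ms consistently with the field equations). Also reports the
#' effective linear coefficient `-alpha + Omega_st`, which is small and
#' positive near self-organized criticality.
#'
#' @param sfp An [stp_field_params()].
#' @param u_quad Quadratic coefficient of the activity equation.
#' @return List `E_st`, `Omega_st`, `gamma_eff` (= `-alpha + Omega_st`).
#' @export
stationary_intersection <- function(sfp, u_quad = 1) {
  a <- sfp$alpha_decay; O0 <- sfp$Omega0; qt <- sfp$q * sfp$tau_STP
  if (O0 <= a)
    return(list(E_st = 0, Omega_st = O0, gamma_eff = O0 - a))
  A2 <- u_quad * qt; A1 <- u_quad + a * qt; A0 <- a - O0
  E_st <- (-A1 + sqrt(A1^2 - 4 * A2 * A0)) / (2 * A2)
  Omega_st <- O0 / (1 + qt * E_st)
  list(E_st = E_st, Omega_st = Omega_st, gamma_eff = -a + Omega_st)
}

#' Linear growth rate of spatial modes
#'
#' For the plain DP field about the absorbing state, mode `k` grows at
#' `lambda(k) = gamma - D k^2`. For the depression-coupled field the
#' homogeneous stationary state is perturbed mode by mode and the larger
#' real part of the 2x2 linearization's eigenvalues is returned; negative
#' values at all `k > 0` mean the patterned perturbations decay.
#'
#' @param k Wavenumber(s).
#' @param config A [field_config()] (supplies `D`, `u_quad`, `gamma`).
#' @param sfp Optional [stp_field_params()]; when given, linearize the
#'   coupled system at [stationary_intersection()].
#' @return Tibble `k`, `growth_rate`.
#' @export
dispersion_relation <- function(k, config, sfp = NULL) {
  if (is.null(sfp)) {
    return(tibble::tibble(k = k, growth_rate = config$gamma - config$D * k^2))
  }
  st <- stationary_intersection(sfp, config$u_quad)
  gr <- vapply(k, function(kk) {
    # fast eq. carries 1/tau_m, slow eq. is in plain time
    a11 <- (st$gamma_eff - 2 * config$u_quad * st$E_st -
              config$D * kk^2) / sfp$tau_m
    a12 <- st$E_st / sfp$tau_m
    a21 <- -sfp$q * st$Omega_st
    a22 <- -1 / sfp$tau_STP - sfp$q * st$E_st
    max(Re(eigen(matrix(c(a11, a12, a21, a22), 2, 2, byrow = TRUE),
                 only.values = TRUE)$values))
  }, numeric(1))
  tibble::tibble(k = k, growth_rate = gr)
}
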