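#' Simulate the conductance-based E-I spiking network
#'
#' Exponential-Euler integration of the LIF network (exact conductance
#' decay, forward-Euler voltage update, threshold check after the update,
#' reset to `v_rest` in the same step, postsynaptic jumps delivered at the
#' start of the next step, no axonal delay, no refractory period). External
#' drive is an independent Poisson excitatory spike train per neuron.
#' Optional plasticity hooks: online pair-based STDP on all four synapse
#' classes (all-to-all pairing via exponential traces) and Tsodyks-Markram
#' short-term depression on E-to-E synapses (one efficacy per presynaptic
#' excitatory neuron). Bitwise reproducible for a fixed `seed` and `dt`.
#'
#' @param synapses A `synapse_table` from [build_network()]/[build_ring()].
#' @param drive A [drive_params()] object.
#' @param duration_ms Biological time to simulate (ms).
#' @param dt Time step (ms); keep well below `tau_syn`.
#' @param seed Integer seed; `NULL` continues the caller's RNG stream.
#' @param params A [neuron_params()] object.
#' @param n_exc,n_inh Population sizes (defaults from the network config).
#' @param stdp `NULL` (off) or [stdp_kernels()].
#' @param stp `NULL` (off) or [stp_params()].
#' @param sample_every_ms Sampling interval of the rate/potential series.
#' @param weight_sample_every_ms Sampling interval of the weight series
#'   (only recorded when a plasticity hook is active).
#' @param record_spikes Keep the full spike record (disable for very long
#'   plasticity runs where only the series matter).
#' @param state Optional state of a previous run (element `state` of a
#'   previous result) to resume from; voltages start at rest otherwise.
#' @return A list of class `eicrit_sim`: `spikes` (tibble `t_ms`,
#'   `neuron_id`, `population`), `series` (tibble `t_ms`, `rate_E_hz`,
#'   `rate_I_hz`, `vmean_E_mv`, `vmean_I_mv`, `u_mean`), `weights` (tibble
#'   of class-mean weight trajectories incl. `wEE_eff` and `deltaW`),
#'   `synapses` (with updated weights), `state`, and metadata (`dt`,
#'   `duration_ms`, `seed`, `n_exc`, `n_inh`).
#' @export
simulate_network <- function(synapses, drive, duration_ms, dt = 0.1,
                             seed = NULL,
                             params = neuron_params(),
                             n_exc = attr(synapses, "config")$n_exc,
                             n_inh = attr(synapses, "config")$n_inh,
                             stdp = NULL, stp = NULL,
                             sample_every_ms = 10,
                             weight_sample_every_ms = 100,
                             record_spikes = TRUE, state = NULL) {
  stopifnot(dt > 0, duration_ms >= 0)
  if (is.null(n_exc) || is.null(n_inh))
    abort("population sizes unavailable: pass n_exc/n_inh explicitly")
  ring <- attr(synapses, "ring")
  if (!is.null(ring)) {
    n_exc <- ring$config$n_exc * ring$n_populations
    n_inh <- ring$config$n_inh * ring$n_populations
  }
  n <- n_exc + n_inh
  if (nrow(synapses) && (any(synapses$pre == synapses$post)))
    abort("self-edges are not allowed")
  if (is.null(state)) {
    state <- list(v = rep(params$v_rest, n), ge = rep(0, n), gi = rep(0, n),
                  u = rep(1, n_exc), t_ms = 0)
  }
  stdp_on <- !is.null(stdp)
  stp_on <- !is.null(stp)
  stdp_list <- if (stdp_on) stdp else list()
  res <- with_seed(seed, cpp_lif_simulate(
    n_exc, n_inh,
    as.integer(synapses$pre) - 1L, as.integer(synapses$post) - 1L,
    as.integer(synapses$class) - 1L, as.numeric(synapses$w),
    unclass(params),
    drive$rho_ext_E, drive$rho_ext_I, drive$w_ext,
    duration_ms, dt, sample_every_ms, weight_sample_every_ms,
    stdp_on, stdp_list,
    stp_on, if (stp_on) stp$q else 0, if (stp_on) stp$tau_STP else 1,
    state$v, state$ge, state$gi,
    if (length(state$u)) state$u else numeric(0),
    record_spikes, state$t_ms))
  spikes <- tibble::tibble(
    t_ms = res$spike_t, neuron_id = res$spike_id + 1L,
    population = ifelse(res$spike_id < n_exc, "E", "I"))
  syn2 <- synapses
  syn2$w <- res$w
  out <- list(
    spikes = spikes,
    series = tibble::as_tibble(res$series),
    weights = tibble::as_tibble(res$wseries),
    synapses = syn2,
    state = list(v = res$v, ge = res$ge, gi = res$gi, u = res$u,
                 t_ms = res$t_end_ms),
    dt = dt, duration_ms = duration_ms, seed = seed,
    n_exc = n_exc, n_inh = n_inh, drive = drive, params = params)
  class(out) <- "eicrit_sim"
  out
}

#' @export
print.eicrit_sim <- function(x, ...) {
  cat("<eicrit_sim> ", x$n_exc, " E + ", x$n_inh, " I neurons, ",
      x$duration_ms, " ms at dt = ", x$dt, " ms\n", sep = "")
  cat("  spikes recorded: ", nrow(x$spikes),
      "; mean E rate: ", signif(mean(x$series$rate_E_hz), 4), " Hz\n", sep = "")
  invisible(x)
}

#' Advance the network state by a single time step
#'
#' One exponential-Euler step of the network equations, without plasticity.
#' Useful for inspecting the integrator; [simulate_network()] runs the same
#' update in a compiled loop.
#'
#' @inheritParams simulate_network
#' @param state List with `v`, `ge`, `gi`, `u`, `t_ms`.
#' @return List with the advanced `state` and the `spikes` emitted in the
#'   step (tibble).
#' @export
lif_step <- function(state, synapses, drive, dt, params = neuron_params(),
                     n_exc, n_inh, seed = NULL) {
  sim <- simulate_network(synapses, drive, duration_ms = dt, dt = dt,
                          seed = seed, params = params, n_exc = n_exc,
                          n_inh = n_inh, sample_every_ms = dt,
                          record_spikes = TRUE, state = state)
  list(state = sim$state, spikes = sim$spikes)
}

#' Per-population rate series from a spike record
#'
#' Bins the spike record and reports population rates in Hz
#' (count / (bin width * population size)). The total spike count is
#' conserved: `sum(rate * bin_s * N)` over bins equals the number of
#' spikes.
#'
#' @param spikes Spike tibble (`t_ms`, `neuron_id`, `population`).
#' @param bin Bin width (ms).
#' @param n_exc,n_inh Population sizes.
#' @param t_range Optional time range (ms); defaults to the spike extent.
#' @return Tibble `t_ms` (bin start), `rate_E_hz`, `rate_I_hz`.
#' @export
population_series <- function(spikes, bin, n_exc, n_inh,
                              t_range = NULL) {
  stopifnot(bin > 0)
  if (nrow(spikes) == 0)
    return(tibble::tibble(t_ms = numeric(), rate_E_hz = numeric(),
                          rate_I_hz = numeric()))
  if (is.null(t_range)) t_range <- c(min(spikes$t_ms), max(spikes$t_ms))
  brk <- seq(t_range[1], t_range[2] + bin, by = bin)
  idx <- findInterval(spikes$t_ms, brk, rightmost.closed = FALSE)
  nb <- length(brk) - 1L
  cntE <- tabulate(idx[spikes$population == "E"], nbins = nb)
  cntI <- tabulate(idx[spikes$population == "I"], nbins = nb)
  tibble::tibble(t_ms = brk[-length(brk)],
                 rate_E_hz = cntE / (bin * 1e-3 * n_exc),
                 rate_I_hz = if (n_inh > 0) cntI / (bin * 1e-3 * n_inh) else 0)
}

#' Read/write spike records as tab-separated text
#'
#' The on-disk dialect is a TSV with header
#' `t_ms<TAB>neuron_id<TAB>population`.
#'
#' @param spikes Spike tibble.
#' @param path File path.
#' @return `read_spikes()` returns the spike tibble.
#' @export
write_spikes <- function(spikes, path) {
  write.table(spikes[c("t_ms", "neuron_id", "population")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "integer", "character"))
  tibble::as_tibble(df)
}
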