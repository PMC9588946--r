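#' Leaky integrate-and-fire neuron parameters
#'
#' Conductance-based LIF neuron with instantaneous-rise, exponential-decay
#' synapses. The membrane obeys
#' \deqn{C\,dv/dt = g_L(v_L - v) + g_{inh}(V_{R,inh} - v) + g_{exc}(V_{R,exc} - v)}
#' and spikes with immediate reset to `v_rest` (no refractory period) when
#' `v` reaches `v_th`. The leak conductance is normalized to 1 so that
#' `C = tau_m * g_leak`; only the membrane time constant is physically
#' meaningful.
#'
#' @param v_th Firing threshold (mV).
#' @param v_rest Reset potential (mV), equal to the leak reversal `v_leak`.
#' @param v_leak Leak reversal potential (mV).
#' @param V_R_exc,V_R_inh Excitatory / inhibitory synaptic reversal
#'   potentials (mV).
#' @param tau_syn_exc,tau_syn_inh Synaptic conductance decay constants (ms).
#' @param tau_m Membrane time constant (ms); the capacitance is
#'   `tau_m * g_leak`.
#' @param g_leak Leak conductance (conductance unit; all synaptic
#'   conductances are expressed relative to it).
#' @param g0_exc,g0_inh Conductance increment per unit synaptic weight. The
#'   default is calibrated once (see [calibrate_g0()]) so that 14
#'   synchronous excitatory spikes of weight 0.54 depolarize a resting
#'   neuron exactly to threshold, placing the reference weight table in the
#'   10--20 synchronous-spike regime.
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(v_th = -50, v_rest = -65, v_leak = -65,
                          V_R_exc = 0, V_R_inh = -80,
                          tau_syn_exc = 5, tau_syn_inh = 5,
                          tau_m = 20, g_leak = 1,
                          g0_exc = eicrit_g0_default, g0_inh = g0_exc) {
  p <- list(v_th = v_th, v_rest = v_rest, v_leak = v_leak,
            V_R_exc = V_R_exc, V_R_inh = V_R_inh,
            tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
            tau_m = tau_m, g_leak = g_leak, g0_exc = g0_exc, g0_inh = g0_inh,
            C = tau_m * g_leak)
  stopifnot(p$v_leak < p$v_th, p$V_R_inh <= p$v_leak, p$v_th <= p$V_R_exc,
            tau_syn_exc > 0, tau_syn_inh > 0, tau_m > 0, g_leak > 0,
            g0_exc > 0, g0_inh > 0)
  structure(p, class = "neuron_params")
}

# frozen default conductance scale: see calibrate_g0(); recomputable at any
# time via calibrate_g0(neuron_params(g0_exc = 1)) / (14 * 0.54) scaling.
eicrit_g0_default <- 0.22755913

#' Single-neuron voltage response to synchronous excitatory input
#'
#' Integrates the membrane equation of a neuron at rest receiving `k`
#' simultaneous excitatory spikes of weight `w` at time 0 (initial
#' excitatory conductance `k * w * g0_exc`), with no further input, and
#' returns the peak depolarization. Spiking/reset is not applied, so the
#' peak may exceed threshold. Exponential-Euler integration; `dt = 0.01` ms
#' resolves the 5 ms conductance decay to well under 0.1 mV voltage error.
#'
#' @param k Number of synchronous presynaptic spikes.
#' @param w Synaptic weight of each spike.
#' @param params A [neuron_params()] object.
#' @param dt Integration step (ms).
#' @param t_max Integration horizon (ms).
#' @return Peak membrane potential (mV).
#' @export
peak_depolarization <- function(k, w, params = neuron_params(),
                                dt = 0.01, t_max = 60) {
  p <- params
  n <- ceiling(t_max / dt)
  g <- k * w * p$g0_exc
  de <- exp(-dt / p$tau_syn_exc)
  v <- p$v_rest
  vmax <- v
  for (i in seq_len(n)) {
    v <- v + dt * (p$g_leak * (p$v_leak - v) + g * (p$V_R_exc - v)) / p$C
    g <- g * de
    if (v > vmax) vmax <- v
  }
  vmax
}

#' Minimal synchronous spike count reaching threshold
#'
#' Smallest number of simultaneous presynaptic excitatory spikes at weight
#' `w` whose peak depolarization from rest reaches the firing threshold.
#'
#' @inheritParams peak_depolarization
#' @param k_max Search bound.
#' @return Integer spike count, or `NA` if `k_max` spikes do not suffice.
#' @export
min_spikes_to_threshold <- function(w, params = neuron_params(),
                                    dt = 0.01, k_max = 200) {
  tol <- 1e-6
  for (k in seq_len(k_max)) {
    if (peak_depolarization(k, w, params, dt = dt) >= params$v_th - tol)
      return(k)
  }
  NA_integer_
}

#' Calibrate the excitatory weight scale to the synchronous-spike rule
#'
#' Cortical synapses are such that 10--20 synchronous excitatory spikes
#' bring a resting neuron to threshold. `calibrate_weights()` returns
#' log-normal weight parameters whose mean `w` satisfies: `n_target`
#' simultaneous spikes of weight `w` produce a peak depolarization exactly
#' at `v_th`. `calibrate_g0()` performs the dual calibration: it fixes the
#' conductance increment `g0_exc` so that a *given* mean weight (default
#' 0.54, the reference baseline E-to-E weight) satisfies the same rule,
#' which lets printed weight tables be used verbatim.
#'
#' @param params A [neuron_params()] object.
#' @param n_target Synchronous spike count that should exactly reach
#'   threshold (default 14, approximately `sqrt(k_EE)` for the full-scale
#'   in-degree of 200; inside the 10--20 band).
#' @param cv Coefficient of variation of the log-normal weight law
#'   (default 0.2, a low-variance distribution).
#' @return For `calibrate_weights()`: a list with `meanlog`, `sdlog`,
#'   `mean`, `cv`, `n_target`. For `calibrate_g0()`: the calibrated
#'   `g0_exc` value.
#' @export
calibrate_weights <- function(params = neuron_params(), n_target = 14,
                              cv = 0.2) {
  stopifnot(n_target >= 1)
  # peak depolarization is monotone in total initial conductance, so a
  # scalar root in the mean weight suffices
  f <- function(w) peak_depolarization(n_target, w, params) - params$v_th
  upper <- 10
  if (f(upper) < 0)
    abort("calibration error: threshold unreachable with the given reversal potentials")
  w_mean <- uniroot(f, c(1e-6, upper), tol = 1e-10)$root
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(w_mean) - sdlog^2 / 2, sdlog = sdlog,
       mean = w_mean, cv = cv, n_target = n_target)
}

#' @rdname calibrate_weights
#' @param w_mean Mean excitatory weight that `n_target` synchronous spikes
#'   should bring exactly to threshold.
#' @export
calibrate_g0 <- function(params = neuron_params(g0_exc = 1), n_target = 14,
                         w_mean = 0.54) {
  base <- neuron_params(g0_exc = 1,
                        v_th = params$v_th, v_rest = params$v_rest,
                        v_leak = params$v_leak, V_R_exc = params$V_R_exc,
                        V_R_inh = params$V_R_inh,
                        tau_syn_exc = params$tau_syn_exc,
                        tau_syn_inh = params$tau_syn_inh,
                        tau_m = params$tau_m, g_leak = params$g_leak)
  f <- function(g0) {
    pp <- base; pp$g0_exc <- g0
    peak_depolarization(n_target, w_mean, pp) - params$v_th
  }
  if (f(100) < 0)
    abort("calibration error: threshold unreachable with the given reversal potentials")
  uniroot(f, c(1e-6, 100), tol = 1e-10)$root
}

#' Closed-form LIF inter-spike interval under constant conductance
#'
#' With constant excitatory conductance `g` the membrane relaxes toward
#' `v_inf = (g_L v_L + g V_{R,exc}) / (g_L + g)` with effective time
#' constant `C / (g_L + g)`; when `v_inf > v_th` the neuron fires
#' periodically with period
#' \deqn{T = \tau_{eff} \log\frac{v_\infty - v_{rest}}{v_\infty - v_{th}}.}
#'
#' @param g Constant excitatory conductance.
#' @param params A [neuron_params()] object.
#' @return Inter-spike interval (ms); `Inf` if subthreshold.
#' @export
lif_isi_constant_g <- function(g, params = neuron_params()) {
  p <- params
  v_inf <- (p$g_leak * p$v_leak + g * p$V_R_exc) / (p$g_leak + g)
  if (v_inf <= p$v_th) return(Inf)
  tau_eff <- p$C / (p$g_leak + g)
  tau_eff * log((v_inf - p$v_rest) / (v_inf - p$v_th))
}
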