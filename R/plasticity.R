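#' STDP kernel pair for excitatory-type and inhibitory-type synapses
#'
#' Pair-based spike-timing-dependent plasticity. For a pre/post spike pair
#' with lag `dt = t_post - t_pre`, the weight changes by
#' `A_plus * exp(-dt / tau_plus)` when `dt >= 0` (potentiation; a
#' simultaneous pair counts as causal) and by
#' `-A_minus * exp(dt / tau_minus)` when `dt < 0`. The kernel class is set
#' by the presynaptic neuron: excitatory presynapses (EE, IE edges) use the
#' E-type kernel, inhibitory presynapses (EI, II) the I-type kernel.
#' Stability of the balanced state requires a net-negative E-type kernel
#' integral `A_plus*tau_plus - A_minus*tau_minus < 0` and a net-positive
#' I-type integral; only these signs are constrained, the shapes are free.
#' Weight dependence is absorbed into constant amplitudes; weights are
#' hard-clipped to `[0, w_max]` per class.
#'
#' @param A_plus_E,A_minus_E,tau_plus_E,tau_minus_E E-type kernel
#'   amplitudes and time constants (ms).
#' @param A_plus_I,A_minus_I,tau_plus_I,tau_minus_I I-type kernel.
#' @param w_max_E,w_max_I Hard weight bounds per kernel class.
#' @param check Verify the kernel-integral sign conditions.
#' @return A list of class `stdp_kernels`.
#' @export
stdp_kernels <- function(A_plus_E = 0.01, A_minus_E = 1.05 * A_plus_E,
                         tau_plus_E = 20, tau_minus_E = 20,
                         A_plus_I = 0.01, A_minus_I = 0.95 * A_plus_I,
                         tau_plus_I = 20, tau_minus_I = 20,
                         w_max_E = 2.16, w_max_I = 8, check = TRUE) {
  k <- list(A_plus_E = A_plus_E, A_minus_E = A_minus_E,
            tau_plus_E = tau_plus_E, tau_minus_E = tau_minus_E,
            A_plus_I = A_plus_I, A_minus_I = A_minus_I,
            tau_plus_I = tau_plus_I, tau_minus_I = tau_minus_I,
            w_max_E = w_max_E, w_max_I = w_max_I)
  stopifnot(all(unlist(k) > 0))
  if (check) {
    if (kernel_integral(k, "E") >= 0)
      abort("E-type kernel integral must be negative")
    if (kernel_integral(k, "I") <= 0)
      abort("I-type kernel integral must be positive")
  }
  structure(k, class = "stdp_kernels")
}

#' @rdname stdp_kernels
#' @param kernels An `stdp_kernels` object.
#' @param type `"E"` or `"I"`.
#' @return For `kernel_integral()`: the signed kernel integral
#'   `A_plus*tau_plus - A_minus*tau_minus` (ms).
#' @export
kernel_integral <- function(kernels, type = c("E", "I")) {
  type <- match.arg(type)
  if (type == "E")
    kernels$A_plus_E * kernels$tau_plus_E - kernels$A_minus_E * kernels$tau_minus_E
  else
    kernels$A_plus_I * kernels$tau_plus_I - kernels$A_minus_I * kernels$tau_minus_I
}

#' Causal spike-train correlation kernel
#'
#' One-sided exponential kernel encoding the excess (anti)correlation of a
#' presynaptic spike arriving `delta` ms before a postsynaptic one:
#' `gamma(delta) = exp(-delta/tau_gamma)/tau_gamma` for `delta >= 0`, zero
#' otherwise (unit integral). Used only by the averaged weight-evolution
#' equations; the spiking simulator generates its own correlations.
#'
#' @param tau_gamma Decay constant (ms), default equal to the synaptic
#'   decay constant.
#' @return A list of class `correlation_kernel` with `tau_gamma` and the
#'   integral `gamma_bar` (= 1 by normalization).
#' @export
correlation_kernel <- function(tau_gamma = 5) {
  stopifnot(tau_gamma > 0)
  structure(list(tau_gamma = tau_gamma, gamma_bar = 1),
            class = "correlation_kernel")
}

# integral of A_plus * exp(-d/tau_plus) * gamma(d) over d >= 0
kplus_gamma_integral <- function(kernels, corr, type = c("E", "I")) {
  type <- match.arg(type)
  Ap <- if (type == "E") kernels$A_plus_E else kernels$A_plus_I
  tp <- if (type == "E") kernels$tau_plus_E else kernels$tau_plus_I
  Ap * tp / (tp + corr$tau_gamma)
}

#' Short-term depression parameters (Tsodyks-Markram)
#'
#' Per presynaptic excitatory neuron `j`, the available-resource fraction
#' `u_j` multiplies all its outgoing E-to-E weights. Each spike of `j`
#' depletes `u_j` by the factor `1 - q`; between spikes `u_j` recovers
#' toward 1 with time constant `tau_STP`:
#' \deqn{du/dt = (1 - u)/\tau_{STP} - q\,u \sum_k \delta(t - t_k).}
#'
#' @param q Depression fraction per spike, in (0, 1).
#' @param tau_STP Recovery time constant (ms); of order 100 ms to seconds,
#'   much slower than the synaptic decay.
#' @param w0_EE Baseline (fully recovered) mean E-to-E weight.
#' @return A list of class `stp_params`.
#' @export
stp_params <- function(q = 0.3, tau_STP = 50, w0_EE = 0.54) {
  stopifnot(q > 0, q < 1, tau_STP > 0)
  structure(list(q = q, tau_STP = tau_STP, w0_EE = w0_EE),
            class = "stp_params")
}

#' Elementary STP updates
#'
#' `stp_on_pre_spike()` applies the per-spike depletion `u -> u (1 - q)`;
#' `stp_decay()` the recovery `u -> 1 + (u - 1) exp(-dt/tau_STP)`;
#' `effective_weight()` the resulting transmitted weight `u * w`
#' (E-to-E edges only).
#'
#' @param u Efficacy in (0, 1].
#' @param q Depression fraction per spike.
#' @param dt Elapsed time (ms).
#' @param tau_STP Recovery time constant (ms).
#' @param w Weight.
#' @export
stp_on_pre_spike <- function(u, q) u * (1 - q)

#' @rdname stp_on_pre_spike
#' @export
stp_decay <- function(u, dt, tau_STP) 1 + (u - 1) * exp(-dt / tau_STP)

#' @rdname stp_on_pre_spike
#' @export
effective_weight <- function(w, u) u * w

#' Stationary efficacy under Poisson presynaptic firing
#'
#' Long-run mean of the jump-decay efficacy process under a Poisson spike
#' train of rate `rate_hz`: `1 / (1 + tau_STP * q * rate)`.
#'
#' @param rate_hz Presynaptic rate (Hz).
#' @inheritParams stp_on_pre_spike
#' @export
stp_stationary_efficacy <- function(rate_hz, q, tau_STP) {
  1 / (1 + tau_STP * 1e-3 * q * rate_hz)
}

# ---------------------------------------------------------------------------
# trace realization of pair-based STDP at the R level (reference path; the
# network simulator runs the same scheme in compiled code)

#' Exponential-trace state for online STDP
#'
#' One presynaptic trace per neuron (decaying with its own kernel's
#' `tau_plus`) and two postsynaptic traces per neuron (one per kernel
#' class). All-to-all pairing: traces sum the contributions of every past
#' spike.
#'
#' @param n_exc,n_inh Population sizes.
#' @return A list of class `trace_state`.
#' @export
trace_state <- function(n_exc, n_inh) {
  n <- n_exc + n_inh
  structure(list(n_exc = n_exc, n_inh = n_inh, t_ms = 0,
                 pre = numeric(n), post_E = numeric(n), post_I = numeric(n)),
            class = "trace_state")
}

#' @rdname trace_state
#' @param traces A `trace_state`.
#' @param dt Time to advance (ms).
#' @param kernels An [stdp_kernels()] object.
#' @export
trace_decay <- function(traces, dt, kernels) {
  exc <- seq_len(traces$n_exc)
  traces$pre[exc] <- traces$pre[exc] * exp(-dt / kernels$tau_plus_E)
  traces$pre[-exc] <- traces$pre[-exc] * exp(-dt / kernels$tau_plus_I)
  traces$post_E <- traces$post_E * exp(-dt / kernels$tau_minus_E)
  traces$post_I <- traces$post_I * exp(-dt / kernels$tau_minus_I)
  traces$t_ms <- traces$t_ms + dt
  traces
}

#' Online STDP update for one spike
#'
#' Applies the weight changes a single spike of `neuron` induces through
#' all-to-all trace pairing, in the given `role`: as a postsynaptic spike
#' it potentiates every in-edge by `A_plus *` (presynaptic trace); as a
#' presynaptic spike it depresses every out-edge by `A_minus *`
#' (postsynaptic trace of the matching kernel class). Traces must already
#' be decayed to the current time; bumping the spiking neuron's own traces
#' is a separate step ([trace_bump()]) so a simultaneous pre/post pair can
#' be routed to the potentiation branch.
#'
#' @param traces A [trace_state()].
#' @param synapses A `synapse_table`.
#' @param kernels An [stdp_kernels()].
#' @param neuron Spiking neuron id.
#' @param role `"post"` (potentiation of in-edges) or `"pre"` (depression
#'   of out-edges).
#' @return Tibble of weight deltas: `edge` (row index in `synapses`),
#'   `dw`, and the clipped new weight `w_new`.
#' @export
stdp_on_spike <- function(traces, synapses, kernels, neuron,
                          role = c("post", "pre")) {
  role <- match.arg(role)
  if (!all(as.character(synapses$class) %in% c("EE", "EI", "IE", "II")))
    abort("configuration error: unknown synapse class")
  e_kernel <- synapses$class %in% c("EE", "IE")  # excitatory presynapse
  if (role == "post") {
    idx <- which(synapses$post == neuron)
    if (!length(idx)) return(tibble::tibble(edge = integer(), dw = numeric(),
                                            w_new = numeric()))
    Ap <- ifelse(e_kernel[idx], kernels$A_plus_E, kernels$A_plus_I)
    dw <- Ap * traces$pre[synapses$pre[idx]]
    wmax <- ifelse(e_kernel[idx], kernels$w_max_E, kernels$w_max_I)
    w_new <- pmin(synapses$w[idx] + dw, wmax)
  } else {
    idx <- which(synapses$pre == neuron)
    if (!length(idx)) return(tibble::tibble(edge = integer(), dw = numeric(),
                                            w_new = numeric()))
    Am <- ifelse(e_kernel[idx], kernels$A_minus_E, kernels$A_minus_I)
    y <- ifelse(e_kernel[idx], traces$post_E[synapses$post[idx]],
                traces$post_I[synapses$post[idx]])
    dw <- -Am * y
    w_new <- pmax(synapses$w[idx] + dw, 0)
  }
  tibble::tibble(edge = idx, dw = dw, w_new = w_new)
}

#' @rdname trace_state
#' @param neuron Spiking neuron id whose traces are incremented by one.
#' @export
trace_bump <- function(traces, neuron) {
  traces$pre[neuron] <- traces$pre[neuron] + 1
  traces$post_E[neuron] <- traces$post_E[neuron] + 1
  traces$post_I[neuron] <- traces$post_I[neuron] + 1
  traces
}

# ---------------------------------------------------------------------------
# averaged weight-evolution layer

#' Right-hand side of the averaged weight-evolution equations
#'
#' Mean-field reduction of STDP in the asynchronous Poisson-firing regime.
#' With population rates `rho` (Hz), mean weights `w`, mean potentials
#' `vbar` (mV), kernel integrals `Khat` and causal-correlation integrals,
#' the four class-mean weights evolve as
#' \deqn{\dot w_{EE} = \rho_E^2 \hat K^E + \rho_E w_{EE}(V_{R,exc}-\langle V_E\rangle)\overline{K_+^E\gamma^E}}
#' and correspondingly for the EI, IE, II classes (I-type kernel and
#' reversed sign of the correlation term for inhibitory presynapses).
#' Rates are converted to 1/ms internally, so the derivatives are per ms.
#'
#' @param rho Named numeric `c(E = , I = )`, rates in Hz.
#' @param w Named numeric `c(EE = , EI = , IE = , II = )`.
#' @param kernels An [stdp_kernels()].
#' @param corr A [correlation_kernel()].
#' @param vbar Named numeric `c(E = , I = )`, mean membrane potentials (mV).
#' @param params A [neuron_params()] (reversal potentials).
#' @return Named numeric of the four weight derivatives (per ms). The
#'   weights of this averaged layer are in the arbitrary units set by the
#'   correlation-kernel normalization; ratios and convergence behaviour,
#'   not absolute values, are the meaningful outputs.
#' @export
mean_weight_ode_rhs <- function(rho, w, kernels, corr, vbar,
                                params = neuron_params()) {
  stopifnot(all(rho >= 0))
  rE <- rho[["E"]] * 1e-3; rI <- rho[["I"]] * 1e-3  # per-ms rates
  KE <- kernel_integral(kernels, "E"); KI <- kernel_integral(kernels, "I")
  KgE <- kplus_gamma_integral(kernels, corr, "E")
  KgI <- kplus_gamma_integral(kernels, corr, "I")
  c(EE = rE^2 * KE + rE * w[["EE"]] * (params$V_R_exc - vbar[["E"]]) * KgE,
    EI = rE * rI * KI - rI * w[["EI"]] * (vbar[["E"]] - params$V_R_inh) * KgI,
    IE = rE * rI * KE + rE * w[["IE"]] * (params$V_R_exc - vbar[["I"]]) * KgE,
    II = rI^2 * KI - rI * w[["II"]] * (vbar[["I"]] - params$V_R_inh) * KgI)
}

#' Stationary coupling-ratio implied by the kernels
#'
#' At a stationary point of the averaged weight dynamics the coupling
#' coefficients satisfy `c_EI/c_EE = c_II/c_IE`, with the common value
#' fixed (up to the degree ratio) by
#' \deqn{\frac{\hat K^I\,\overline{K_+^E\gamma^E}}{\hat K^E\,\overline{K_+^I\gamma^I}}.}
#' Under the stability sign conditions the ratio is negative, consistent
#' with inhibitory coupling coefficients being negative.
#'
#' @inheritParams mean_weight_ode_rhs
#' @return The scalar ratio.
#' @export
stationary_ratio_from_kernels <- function(kernels, corr = correlation_kernel()) {
  KE <- kernel_integral(kernels, "E"); KI <- kernel_integral(kernels, "I")
  if (KE >= 0 || KI <= 0)
    abort("stability violation: need E-type kernel integral < 0 and I-type > 0")
  (KI * kplus_gamma_integral(kernels, corr, "E")) /
    (KE * kplus_gamma_integral(kernels, corr, "I"))
}
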