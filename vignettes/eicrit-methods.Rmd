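---
title: "eicrit: models, numerics and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eicrit: models, numerics and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model definitions, parameter conventions,
numerical schemes and known limitations behind `eicrit`. It is the reference
for anyone interpreting the package's outputs or extending it.

## 1. The spiking network

### Neuron model

Each neuron is a conductance-based leaky integrate-and-fire unit:

$$ C \frac{dv}{dt} = -g_L (v - v_\mathrm{leak})
   - g_E(t)\,(v - V_{R,\mathrm{exc}}) - g_I(t)\,(v - V_{R,\mathrm{inh}}), $$

with exponentially decaying synaptic conductances
$\tau_\mathrm{syn}\,\dot g_{E/I} = -g_{E/I}$ that jump by $g_0 w$ on each
presynaptic spike of weight $w$. Defaults: $v_\mathrm{rest} = v_\mathrm{leak}
= -65$ mV, threshold $v_\mathrm{th} = -50$ mV, reset to rest,
$V_{R,\mathrm{exc}} = 0$ mV, $V_{R,\mathrm{inh}} = -80$ mV,
$\tau_m = C/g_L = 20$ ms, $\tau_\mathrm{syn} = 5$ ms, **no refractory
period**.

The conductance scale $g_0$ is not free: it is calibrated so that a fixed
number of synchronous excitatory spikes at the mean weight lifts a resting
neuron exactly to threshold (`calibrate_g0()`, `min_spikes_to_threshold()`).
With the default mean E→E weight of 0.54 the calibrated $g_0$ puts that
count at 14 spikes, inside the intended 10–20 band. The single-EPSP peak
has a closed form used both by the calibration and its tests.

### Network and drive

`network_config()`/`build_network()` draw fixed in-degree random graphs for
the four synapse classes (EE, EI, IE, II) with truncated-Gaussian weights
(default CV 0.2). All randomness is owned by the config seed. External input
is independent Poisson drive per neuron (`drive_params()`), delivered through
the same conductance machinery.

### Integration scheme

`simulate_network()` advances with a fixed step (default $dt = 0.1$ ms) using
exponential (exact) decay for conductances, plasticity traces and STP
variables, and forward Euler for the voltage — the standard exponential-Euler
splitting for conductance LIF models. Spikes are detected by threshold
crossing at step boundaries; because there is no refractory period, a
neuron's rate is capped at $1/dt = 10$ kHz (see Limitations). The simulator
supports state checkpoint/resume, which the tests use to verify that a split
run is bitwise identical to an unsplit one.

## 2. Plasticity

### STDP

Pair-based kernels with exponential potentiation/depression branches
(`stdp_kernels()`), applied to all four synapse classes; E-type kernels have
negative integral (net depression), I-type positive. The online
implementation keeps one pre- and one post-trace per neuron and is exactly
equivalent to the explicit all-pairs double sum — the tests assert agreement
to 1e-10 on 1 s spike records. Weights are clipped to $[0, w_\mathrm{max}]$.

### Short-term depression

E→E synapses carry a depression variable with recovery time
$\tau_\mathrm{STP}$ and utilization $q$ (`stp_params()`; defaults $q = 0.3$,
$\tau_\mathrm{STP} = 10\,\tau_\mathrm{syn} = 50$ ms). For a *Poisson*
presynaptic train of rate $\rho$ the stationary efficacy has the closed form
$1/(1 + q\,\tau_\mathrm{STP}\,\rho)$ (`stp_stationary_efficacy()`). This
formula is exact only for Poisson statistics; network-generated trains are
non-Poisson and deviate by several percent, which is why the oracle test
drives the depression process with a synthetic Poisson train.

## 3. Mean field and the organizing point

`meanfield_params()` defines the two-population rate model
$\tau\,\dot\rho_a = -\rho_a + G(z_a)$ with a smooth sigmoidal gain fitted to
the single-neuron f–I response (`calibrate_gain()`), and coupling
coefficients derived from degrees, weights and the synaptic/membrane
conductance scales. `find_fixed_points()` brackets and polishes fixed points,
classifies them through the Jacobian, and labels the quiescent/low/middle/high
branches. `bt_residuals()` reports the distance of a parameter set from the
double-zero (Bogdanov–Takens) degeneracy — trace and determinant of the
Jacobian together with the weight-balance residual
$\Delta W = W_{EE} k_{EE}/k_{EI} - W_{EI} W_{IE} \cdot (\dots)$ reported as
`deltaW`. The slow–fast system (`slow_fast_rhs()`, `stationary_wEE()`)
couples the rate equations to the averaged STDP weight drift and shows the
self-organized stationary effective E→E weight.

## 4. Finite-size fluctuations

`markov_config()` defines a two-species birth–death Markov process for the
population activities with system sizes $N_E$, $N_I$. `lna_variances()`
computes the linear noise approximation: the Jacobian $A$ and diffusion $B$
at the deterministic fixed point and the stationary covariance from the
Lyapunov equation $A S + S A^\top + B = 0$. `simulate_markov()` is an exact
Gillespie implementation in compiled code with time-weighted moment
accumulation. The acceptance test checks LNA against six independent
Gillespie replicas within three standard errors; `variance_vs_criticality()`
shows the divergence of scaled variances on approach to instability.

## 5. The Langevin field layer

`simulate_dp_field()` integrates
$$ \tau\,\partial_t E = \gamma E - u E^2 + D \nabla^2 E + \sigma(E)\,\xi, \qquad
   \sigma^2(E) = \frac{2\sigma^2}{N_\mathrm{local}\,dx}\,E, $$
the Langevin equation of the directed-percolation (absorbing-state)
universality class. Multiplicative square-root noise cannot be integrated
with naive Euler–Maruyama: clipping negative excursions rectifies the noise
into a spurious immigration term that keeps avalanches alive forever. The
package instead uses an operator-splitting scheme: the deterministic
(reaction–diffusion) part is stepped explicitly and the linear-plus-noise
part is sampled *exactly* from its known transition density, a
Poisson-mixed Gamma distribution. With this propagator the absorbing state
$E \equiv 0$ is exactly invariant, point-seeded critical avalanches die in
finite time, and the size distribution reproduces the mean-field DP exponent
3/2. The explicit diffusion step enforces the stability bound
$D\,dt/dx^2 \le 1/4$. `rescale_to_dp()` maps parameters to the one-parameter
normal form; `simulate_stp_field()` couples the field to a slow
depression-dynamics efficacy whose stationary state is the intersection of
the two nullcline branches (`stationary_intersection()`).

The quadratic coefficient controls the scaling window: with the seed scale
fixed by the initial condition and the cutoff at $E \sim \gamma/u$, a small
$u$ (the tests use 0.02) keeps several decades of sizes between the
microscopic scale and the nonlinear cutoff, which is what makes the 3/2
exponent measurable with 5000 avalanches.

## 6. Avalanche statistics

`detect_avalanches()` bins event times on an **absolute** grid (bin edges at
integer multiples of the bin width, not anchored at the first event) and
defines avalanches as runs of occupied bins between empty bins. Absolute
anchoring matters: anchoring at the first event biases the segmentation and
noticeably biases the bin-ratio branching estimator on sub-critical data.
The default bin width is the mean inter-event interval.

`fit_power_law()` implements the discrete MLE with the Hurwitz-zeta
normalization $P(X = x) = x^{-\alpha}/\zeta(\alpha, x_\mathrm{min})$, an
exact CDF $P(X \le x) = 1 - \zeta(\alpha, x+1)/\zeta(\alpha, x_\mathrm{min})$
for Kolmogorov–Smirnov distances, KS-minimizing $x_\mathrm{min}$ selection,
and a log-log CCDF regression alternative. `branching_ratio()` offers the
bin-ratio estimator (consecutive occupied-bin count ratios) and a causal
window estimator. `shape_collapse()` scans the collapse exponent minimizing
the variance across rescaled mean temporal profiles; `size_duration_scaling()`
fits $\langle S \rangle \sim T^2$ on the critical fixture.

## 7. Synthetic fixtures as oracles

Every estimator is tested against a generator whose ground truth is known by
construction, not against the network:

- `poisson_train()` — exact exponential inter-event sampling (rate, ISI CV 1).
- `branching_avalanches()` — Galton–Watson cascades laid out on a bin grid
  with guaranteed quiescent gaps and a truth catalog (sizes, durations), so
  segmentation can be checked *exactly* and offspring means (0.3, 0.8, 1.0)
  recovered.
- `power_law_samples()` — exact discrete zeta sampling by inversion; the
  probabilities of the smallest values have closed forms used in tests.

## 8. Reproducibility conventions

One global seed plus `derive_seed(seed, label)` (a deterministic hash of the
label into a substream seed) gives every module an independent stream, so
enabling an analysis option never perturbs simulation randomness. All
experiment bundles written by `run_experiment()` contain the resolved config,
the seed and the package version in `manifest.json`; re-running with the same
seed reproduces every table byte-for-byte.

## 9. Limitations

- **Desk scale is sub-critical.** The reference avalanche-regime figures use
  $N_\mathrm{exc} = 2\times 10^4$ with in-degrees 200/50. The package's
  acceptance-scale network (2000/500, degrees 20/5) preserves the mean input
  per neuron but has ten times fewer recurrent inputs per neuron, so
  finite-size fluctuations are stronger and the self-organized state sits
  measurably below criticality: CCDF size exponents come out near 2.6
  (MLE near 1.6) instead of 1.5, and the bin-ratio branching ratio near 0.77
  instead of 0.8–1. These are properties of the scaled-down operating point,
  not of the estimators — the same estimators recover exact Galton–Watson
  and directed-percolation ground truths to within their standard errors.
- **No refractory period.** Rates in the no-STP high-activity state are
  limited only by the integration step ($1/dt$), so the "ceiling" state is
  dt-dependent and far above the mean-field limit-cycle average; the
  high-activity acceptance check documents this.
- **Poisson-only STP formula.** The stationary-efficacy closed form assumes
  Poisson presynaptic statistics (see §2).
- **Mean-field DP exponents.** The Langevin field is integrated in one
  dimension at mean-field parameter strength; the 3/2 size exponent is the
  mean-field value, not the 1d DP value.
- The gain calibration is frozen at package defaults; recalibrating for other
  neuron parameters is supported (`calibrate_gain()`) but not automatic.
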