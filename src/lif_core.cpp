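#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Synapse class codes used throughout: 0 = EE (E<-E), 1 = EI (E<-I),
// 2 = IE (I<-E), 3 = II (I<-I). Pre-neuron type decides the STDP kernel
// class: excitatory presynapse (EE, IE) -> E-kernel, inhibitory (EI, II)
// -> I-kernel.

static inline bool pre_is_exc(int cls) { return cls == 0 || cls == 2; }

// [[Rcpp::export]]
List cpp_lif_simulate(int n_exc, int n_inh,
                      IntegerVector pre, IntegerVector post, IntegerVector cls,
                      NumericVector w_in,
                      List neuron,
                      double rate_ext_e, double rate_ext_i, double w_ext,
                      double duration_ms, double dt,
                      double sample_every_ms, double weight_sample_every_ms,
                      bool stdp_on, List stdp,
                      bool stp_on, double q, double tau_stp,
                      NumericVector v_init, NumericVector ge_init,
                      NumericVector gi_init, NumericVector u_init,
                      bool record_spikes, double t0_ms) {
  const int n = n_exc + n_inh;
  const int m = pre.size();
  const double vL   = neuron["v_leak"];
  const double vth  = neuron["v_th"];
  const double vre  = neuron["v_rest"];
  const double VRe  = neuron["V_R_exc"];
  const double VRi  = neuron["V_R_inh"];
  const double g0e  = neuron["g0_exc"];
  const double g0i  = neuron["g0_inh"];
  const double taue = neuron["tau_syn_exc"];
  const double taui = neuron["tau_syn_inh"];
  const double gL   = neuron["g_leak"];
  const double tm   = neuron["tau_m"];
  const double C    = gL * tm;

  // STDP kernel parameters (amplitudes already include any f+/- constant)
  double ApE = 0, AmE = 0, tpE = 20, tmE = 20, ApI = 0, AmI = 0, tpI = 20,
         tmI = 20, wmaxE = 1e9, wmaxI = 1e9;
  if (stdp_on) {
    ApE = stdp["A_plus_E"];  AmE = stdp["A_minus_E"];
    tpE = stdp["tau_plus_E"]; tmE = stdp["tau_minus_E"];
    ApI = stdp["A_plus_I"];  AmI = stdp["A_minus_I"];
    tpI = stdp["tau_plus_I"]; tmI = stdp["tau_minus_I"];
    wmaxE = stdp["w_max_E"]; wmaxI = stdp["w_max_I"];
  }

  const double de = std::exp(-dt / taue);
  const double di = std::exp(-dt / taui);
  const double ds = (tau_stp > 0) ? std::exp(-dt / tau_stp) : 1.0;
  const long n_steps = (long)std::llround(duration_ms / dt);

  std::vector<double> w(w_in.begin(), w_in.end());
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> ge(ge_init.begin(), ge_init.end());
  std::vector<double> gi(gi_init.begin(), gi_init.end());
  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> pge(n, 0.0), pgi(n, 0.0);

  // CSR by pre, CSC by post (edge index lists)
  std::vector<int> out_off(n + 1, 0), in_off(n + 1, 0);
  for (int e = 0; e < m; ++e) { out_off[pre[e] + 1]++; in_off[post[e] + 1]++; }
  for (int i = 0; i < n; ++i) { out_off[i + 1] += out_off[i]; in_off[i + 1] += in_off[i]; }
  std::vector<int> out_e(m), in_e(m);
  { std::vector<int> oc(out_off.begin(), out_off.end() - 1),
                     ic(in_off.begin(), in_off.end() - 1);
    for (int e = 0; e < m; ++e) { out_e[oc[pre[e]]++] = e; in_e[ic[post[e]]++] = e; } }

  // lazily decayed STDP traces
  std::vector<double> trp(n, 0.0), ypE(n, 0.0), ypI(n, 0.0);
  std::vector<long> trp_s(n, 0), ypE_s(n, 0), ypI_s(n, 0);

  std::vector<double> spike_t; std::vector<int> spike_id;
  std::vector<int> spikers; spikers.reserve(256);

  const long samp_steps = std::max<long>(1, (long)std::llround(sample_every_ms / dt));
  const long wsamp_steps = std::max<long>(1, (long)std::llround(weight_sample_every_ms / dt));
  long cntE = 0, cntI = 0;
  std::vector<double> s_t, s_rE, s_rI, s_vE, s_vI, s_u;
  std::vector<double> ws_t, ws_EE, ws_EI, ws_IE, ws_II, ws_EEeff, ws_dW;

  const double lamE = n_exc * rate_ext_e * dt * 1e-3;  // expected ext E spikes/step
  const double lamI = n_inh * rate_ext_i * dt * 1e-3;

  for (long s = 1; s <= n_steps; ++s) {
    // 1. deliver pending conductance jumps (spikes emitted in the previous step)
    for (int i = 0; i < n; ++i) {
      ge[i] += pge[i]; gi[i] += pgi[i]; pge[i] = 0.0; pgi[i] = 0.0;
    }
    // 2. external Poisson drive (excitatory channel), delivered next step
    if (lamE > 0) {
      int k = (int)R::rpois(lamE);
      for (int j = 0; j < k; ++j) {
        int tgt = (int)(unif_rand() * n_exc); if (tgt >= n_exc) tgt = n_exc - 1;
        pge[tgt] += w_ext * g0e;
      }
    }
    if (lamI > 0) {
      int k = (int)R::rpois(lamI);
      for (int j = 0; j < k; ++j) {
        int tgt = n_exc + (int)(unif_rand() * n_inh); if (tgt >= n) tgt = n - 1;
        pge[tgt] += w_ext * g0e;
      }
    }
    // 3. voltage forward Euler, then exact conductance decay
    for (int i = 0; i < n; ++i) {
      double vi = v[i];
      vi += dt * (gL * (vL - vi) + gi[i] * (VRi - vi) + ge[i] * (VRe - vi)) / C;
      v[i] = vi;
      ge[i] *= de; gi[i] *= di;
    }
    // 4. STP recovery toward full resources
    if (stp_on) for (int i = 0; i < n_exc; ++i) u[i] = 1.0 + (u[i] - 1.0) * ds;
    // 5. threshold crossing and reset
    spikers.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= vth) { v[i] = vre; spikers.push_back(i);
        if (i < n_exc) ++cntE; else ++cntI; }
    }
    if (!spikers.empty()) {
      double tnow = t0_ms + s * dt;
      if (record_spikes)
        for (int sp : spikers) { spike_t.push_back(tnow); spike_id.push_back(sp); }
      if (stdp_on) {
        // pre traces first: simultaneous pre/post pairs land in the
        // potentiation branch (delta-t = 0 counts as causal)
        for (int sp : spikers) {
          double tau = (sp < n_exc) ? tpE : tpI;
          trp[sp] = trp[sp] * std::exp(-((double)(s - trp_s[sp])) * dt / tau) + 1.0;
          trp_s[sp] = s;
        }
        for (int sp : spikers) {  // as postsynaptic: potentiate in-edges
          for (int k = in_off[sp]; k < in_off[sp + 1]; ++k) {
            int e = in_e[k]; int j = pre[e];
            bool eknl = pre_is_exc(cls[e]);
            double tau = eknl ? tpE : tpI, Ap = eknl ? ApE : ApI,
                   wmax = eknl ? wmaxE : wmaxI;
            double tr = trp[j] * std::exp(-((double)(s - trp_s[j])) * dt / tau);
            double wn = w[e] + Ap * tr;
            w[e] = (wn > wmax) ? wmax : wn;
          }
        }
      }
      for (int sp : spikers) {  // as presynaptic: depress, deplete, propagate
        double ueff = (stp_on && sp < n_exc) ? u[sp] : 1.0;
        for (int k = out_off[sp]; k < out_off[sp + 1]; ++k) {
          int e = out_e[k]; int i2 = post[e];
          if (stdp_on) {
            bool eknl = pre_is_exc(cls[e]);
            double tau = eknl ? tmE : tmI, Am = eknl ? AmE : AmI;
            double y = eknl ? ypE[i2] * std::exp(-((double)(s - ypE_s[i2])) * dt / tau)
                            : ypI[i2] * std::exp(-((double)(s - ypI_s[i2])) * dt / tau);
            double wn = w[e] - Am * y;
            w[e] = (wn < 0.0) ? 0.0 : wn;
          }
          double weff = (cls[e] == 0) ? w[e] * ueff : w[e];
          if (pre_is_exc(cls[e])) pge[i2] += weff * g0e; else pgi[i2] += weff * g0i;
        }
        if (stp_on && sp < n_exc) u[sp] *= (1.0 - q);
      }
      if (stdp_on) for (int sp : spikers) {
        ypE[sp] = ypE[sp] * std::exp(-((double)(s - ypE_s[sp])) * dt / tmE) + 1.0;
        ypE_s[sp] = s;
        ypI[sp] = ypI[sp] * std::exp(-((double)(s - ypI_s[sp])) * dt / tmI) + 1.0;
        ypI_s[sp] = s;
      }
    }
    // 6. sampled series
    if (s % samp_steps == 0) {
      double win_s = samp_steps * dt * 1e-3;
      double vE = 0, vI = 0, um = 0;
      for (int i = 0; i < n_exc; ++i) { vE += v[i]; if (stp_on) um += u[i]; }
      for (int i = n_exc; i < n; ++i) vI += v[i];
      s_t.push_back(t0_ms + s * dt);
      s_rE.push_back(cntE / (win_s * n_exc));
      s_rI.push_back(n_inh > 0 ? cntI / (win_s * n_inh) : 0.0);
      s_vE.push_back(vE / n_exc);
      s_vI.push_back(n_inh > 0 ? vI / n_inh : NA_REAL);
      s_u.push_back(stp_on ? um / n_exc : 1.0);
      cntE = 0; cntI = 0;
      if (!R_finite(vE)) stop("non-finite membrane state at t = %f ms", t0_ms + s * dt);
    }
    if ((stdp_on || stp_on) && (s % wsamp_steps == 0 || s == n_steps)) {
      double sw[4] = {0, 0, 0, 0}; long nc[4] = {0, 0, 0, 0};
      double seff = 0; long neff = 0;
      for (int e = 0; e < m; ++e) {
        sw[cls[e]] += w[e]; nc[cls[e]]++;
        if (cls[e] == 0) { seff += w[e] * (stp_on ? u[pre[e]] : 1.0); neff++; }
      }
      double mEE = nc[0] ? sw[0] / nc[0] : 0, mEI = nc[1] ? sw[1] / nc[1] : 0,
             mIE = nc[2] ? sw[2] / nc[2] : 0, mII = nc[3] ? sw[3] / nc[3] : 0,
             mEEeff = neff ? seff / neff : 0;
      ws_t.push_back(t0_ms + s * dt);
      ws_EE.push_back(mEE); ws_EI.push_back(mEI); ws_IE.push_back(mIE);
      ws_II.push_back(mII); ws_EEeff.push_back(mEEeff);
      ws_dW.push_back(mEEeff * mII - mEI * mIE);
    }
  }

  return List::create(
    _["spike_t"] = wrap(spike_t), _["spike_id"] = wrap(spike_id),
    _["series"] = List::create(_["t_ms"] = wrap(s_t), _["rate_E_hz"] = wrap(s_rE),
                               _["rate_I_hz"] = wrap(s_rI), _["vmean_E_mv"] = wrap(s_vE),
                               _["vmean_I_mv"] = wrap(s_vI), _["u_mean"] = wrap(s_u)),
    _["wseries"] = List::create(_["t_ms"] = wrap(ws_t), _["wEE"] = wrap(ws_EE),
                                _["wEI"] = wrap(ws_EI), _["wIE"] = wrap(ws_IE),
                                _["wII"] = wrap(ws_II), _["wEE_eff"] = wrap(ws_EEeff),
                                _["deltaW"] = wrap(ws_dW)),
    _["w"] = wrap(w), _["v"] = wrap(v), _["ge"] = wrap(ge), _["gi"] = wrap(gi),
    _["u"] = wrap(u), _["t_end_ms"] = t0_ms + n_steps * dt);
}

// ---- smooth threshold-linear gain (shared with the R implementation) ----

static inline double softplus(double x, double wdt) {
  double r = x / wdt;
  if (r > 30.0) return x;
  return wdt * std::log1p(std::exp(r));
}

// [[Rcpp::export]]
double cpp_gain_tls(double z, double rmax, double beta, double theta,
                    double width, double z0) {
  double inner = softplus(beta * (z - theta), width);
  double g = rmax - softplus(rmax - inner, width) - z0;
  return g > 0.0 ? g : 0.0;
}

// Two-population birth-death Markov model, exact (Gillespie) simulation.
// State (nE, nI) are counts of active units; intensive activities
// e = nE/NE, i = nI/NI play the role of the population rates. Transition
// rates: activation NE*alpha*G_E(e,i), deactivation alpha*nE (same for I).
// gain_mode 0: G constant (immigration-death oracle); 1: coupled
// threshold-linear-soft gain on z = c1*e + c2*i + drive.
// [[Rcpp::export]]
List cpp_gillespie(int NE, int NI, double alpha,
                   int gain_mode, NumericVector gpar,
                   double cEE, double cEI, double cIE, double cII,
                   double driveE, double driveI,
                   double T_ms, double burnin_ms,
                   int nE0, int nI0, int max_events,
                   int sample_n) {
  double t = 0.0;
  long nE = nE0, nI = nI0;
  // time-weighted moments after burn-in
  double W = 0, Se = 0, Si = 0, See = 0, Sii = 0, Sei = 0;
  std::vector<double> samp_t, samp_e, samp_i;
  double samp_every = (sample_n > 0) ? T_ms / sample_n : -1.0;
  double next_samp = samp_every;
  int n_events = 0;

  while (t < T_ms && n_events < max_events) {
    double e = (double)nE / NE, i = (double)nI / NI;
    double GE, GI;
    if (gain_mode == 0) { GE = gpar[0]; GI = gpar[1]; }
    else {
      GE = cpp_gain_tls(cEE * e + cEI * i + driveE, gpar[0], gpar[1], gpar[2], gpar[3], gpar[4]);
      GI = cpp_gain_tls(cIE * e + cII * i + driveI, gpar[0], gpar[1], gpar[2], gpar[3], gpar[4]);
    }
    double rbE = NE * alpha * GE, rdE = alpha * nE;
    double rbI = NI * alpha * GI, rdI = alpha * nI;
    double R = rbE + rdE + rbI + rdI;
    if (R <= 0) {  // absorbing configuration
      double t_next = T_ms;
      if (t_next > burnin_ms) {
        double dtw = t_next - std::max(t, burnin_ms);
        W += dtw; Se += e * dtw; Si += i * dtw;
        See += e * e * dtw; Sii += i * i * dtw; Sei += e * i * dtw;
      }
      t = t_next; break;
    }
    double dtv = R::rexp(1.0) / R;
    double t_next = t + dtv;
    if (t_next > burnin_ms) {
      double dtw = std::min(t_next, T_ms) - std::max(t, burnin_ms);
      if (dtw > 0) { W += dtw; Se += e * dtw; Si += i * dtw;
        See += e * e * dtw; Sii += i * i * dtw; Sei += e * i * dtw; }
    }
    while (samp_every > 0 && next_samp <= t_next && next_samp <= T_ms) {
      samp_t.push_back(next_samp); samp_e.push_back(e); samp_i.push_back(i);
      next_samp += samp_every;
    }
    t = t_next;
    if (t >= T_ms) break;
    double r = unif_rand() * R;
    if (r < rbE) nE++;
    else if (r < rbE + rdE) nE--;
    else if (r < rbE + rdE + rbI) nI++;
    else nI--;
    ++n_events;
  }
  double me = W > 0 ? Se / W : NA_REAL, mi = W > 0 ? Si / W : NA_REAL;
  return List::create(
    _["mean_e"] = me, _["mean_i"] = mi,
    _["var_e"] = W > 0 ? See / W - me * me : NA_REAL,
    _["var_i"] = W > 0 ? Sii / W - mi * mi : NA_REAL,
    _["cov_ei"] = W > 0 ? Sei / W - me * mi : NA_REAL,
    _["weight_ms"] = W, _["n_events"] = n_events,
    _["t_end_ms"] = t, _["nE_end"] = (double)nE, _["nI_end"] = (double)nI,
    _["path"] = List::create(_["t_ms"] = wrap(samp_t), _["e"] = wrap(samp_e),
                             _["i"] = wrap(samp_i)));
}

// ---- directed-percolation Langevin field (Euler-Maruyama, clip at 0) ----

// One run of the E-field (Eq.-29-type dynamics), 1D ring (ny=1) or 2D
// periodic lattice. tau_time rescales time (tau_m for the STP-coupled
// variant; 1 for the plain DP field).
// [[Rcpp::export]]
// Exact split-step update for the linear + demographic-noise part of the
// DP Langevin equation: dE = lam*E dt + sqrt(g*E) dW has the transition
// law E(dt) = Gamma(Poisson(omega*E0*exp(lam*dt)), 1)/omega with
// omega = 2*lam/(g*(exp(lam*dt)-1)) (-> 2/(g*dt) as lam -> 0), which
// reaches the absorbing state E = 0 with the correct probability; a naive
// Euler-Maruyama step with clipping at zero rectifies the noise and acts
// as spurious immigration that prevents extinction.
static inline double dornic_step(double e_star, double lam, double g,
                                 double dt, long &trunc_count) {
  if (e_star <= 0.0) { if (e_star < 0.0) ++trunc_count; return 0.0; }
  double grow = std::exp(lam * dt);
  if (g <= 0.0) return e_star * grow;
  double omega = (std::fabs(lam) > 1e-12) ? 2.0 * lam / (g * (grow - 1.0))
                                          : 2.0 / (g * dt);
  double n = R::rpois(omega * e_star * grow);
  if (n <= 0.0) return 0.0;
  return R::rgamma(n, 1.0) / omega;
}

List cpp_dp_field(NumericVector E0, int nx, int ny,
                  double dt, double dx, double D,
                  double gamma, double u_quad, double sigma2, double N_local,
                  double drive, long n_steps, int sample_every,
                  bool stop_when_absorbed, double eps,
                  bool stp_on, NumericVector Om0v, double Omega0,
                  double alpha_decay, double q, double tau_stp, double tau_time) {
  const int ns = nx * ny;
  std::vector<double> E(E0.begin(), E0.end()), En(ns);
  std::vector<double> Om;
  if (stp_on) Om.assign(Om0v.begin(), Om0v.end());
  const double dx2 = dx * dx;
  long trunc_count = 0;
  double size_integral = 0.0;  // sum_t sum_x E dt dx
  std::vector<double> s_t, s_E, s_Om;
  long steps_done = 0;
  const double gnoise = 2.0 * sigma2 / (N_local * dx * tau_time * tau_time);

  for (long s = 1; s <= n_steps; ++s) {
    double tot = 0.0;
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int id = iy * nx + ix;
        double e = E[id];
        double lap;
        if (ny == 1) {
          lap = (E[(ix + 1) % nx] + E[(ix - 1 + nx) % nx] - 2.0 * e) / dx2;
        } else {
          lap = (E[iy * nx + (ix + 1) % nx] + E[iy * nx + (ix - 1 + nx) % nx] +
                 E[((iy + 1) % ny) * nx + ix] + E[((iy - 1 + ny) % ny) * nx + ix] -
                 4.0 * e) / dx2;
        }
        double lin = stp_on ? (-alpha_decay + Om[id]) : gamma;
        // deterministic part (nonlinearity, diffusion, drive), then the
        // exact linear + noise propagator
        double e_star = e + (dt / tau_time) *
          (-u_quad * e * e + D * lap + drive);
        En[id] = dornic_step(e_star, lin / tau_time, gnoise, dt, trunc_count);
        tot += En[id];
      }
    }
    if (stp_on) {
      for (int id = 0; id < ns; ++id)
        Om[id] += dt * ((Omega0 - Om[id]) / tau_stp - q * Om[id] * E[id]);
    }
    E.swap(En);
    size_integral += tot * dt * dx;
    steps_done = s;
    if (sample_every > 0 && s % sample_every == 0) {
      s_t.push_back(s * dt); s_E.push_back(tot / ns);
      if (stp_on) {
        double so = 0; for (int id = 0; id < ns; ++id) so += Om[id];
        s_Om.push_back(so / ns);
      }
    }
    if (stop_when_absorbed && tot * dx < eps && drive <= 0.0) break;
    if (!R_finite(tot)) stop("field integration diverged at step %ld", s);
  }
  return List::create(
    _["E"] = wrap(E), _["Omega"] = stp_on ? wrap(Om) : R_NilValue,
    _["steps"] = (double)steps_done, _["size_integral"] = size_integral,
    _["truncations"] = (double)trunc_count,
    _["series"] = List::create(_["t_ms"] = wrap(s_t), _["E_mean"] = wrap(s_E),
                               _["Omega_mean"] = wrap(s_Om)));
}

// Repeated point-seeded avalanches of the DP field at (or near) gamma' = 0.
// [[Rcpp::export]]
List cpp_dp_avalanches(int nx, double dt, double dx, double D,
                       double gamma, double u_quad, double sigma2,
                       double N_local, double seed_value, double eps,
                       long max_steps, int n_avalanches) {
  std::vector<double> sizes(n_avalanches), durations(n_avalanches);
  std::vector<int> truncated(n_avalanches);
  std::vector<double> E(nx), En(nx);
  const double dx2 = dx * dx;
  const double gnoise = 2.0 * sigma2 / (N_local * dx);
  long trunc_clip = 0;
  for (int a = 0; a < n_avalanches; ++a) {
    std::fill(E.begin(), E.end(), 0.0);
    E[nx / 2] = seed_value;
    double size = 0.0; long s = 0; int trunc = 1;
    for (s = 1; s <= max_steps; ++s) {
      double tot = 0.0;
      for (int ix = 0; ix < nx; ++ix) {
        double e = E[ix];
        double lap = (E[(ix + 1) % nx] + E[(ix - 1 + nx) % nx] - 2.0 * e) / dx2;
        double e_star = e + dt * (-u_quad * e * e + D * lap);
        double en = dornic_step(e_star, gamma, gnoise, dt, trunc_clip);
        En[ix] = en; tot += en;
      }
      E.swap(En);
      size += tot * dt * dx;
      if (tot * dx < eps) { trunc = 0; break; }
    }
    sizes[a] = size; durations[a] = s * dt; truncated[a] = trunc;
  }
  return List::create(_["size"] = wrap(sizes), _["duration"] = wrap(durations),
                      _["truncated"] = wrap(truncated));
}
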