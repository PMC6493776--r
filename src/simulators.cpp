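#include <Rcpp.h>
using namespace Rcpp;

// gain evaluation for the rate simulator: 0 = softplus, 1 = threshold-quadratic
static inline double eval_gain(double J, int type, const double *p) {
  if (type == 0) {
    double z = (J - p[1]) / p[2];
    if (z > 30.0) return p[0] * z;
    return p[0] * std::log1p(std::exp(z));
  }
  double h = J - p[1];
  if (h < 0.0) return 0.0;
  double h2 = h * h;
  return p[0] * h2 / (1.0 + h2);
}

// Euler-Maruyama integration of the 3N-dimensional synaptic system with
// multiplicative Poisson-rate noise: the three equations of neuron i share
// one noise increment scaled by sqrt(phi_i).
// [[Rcpp::export]]
List rate_sde_cpp(NumericMatrix Weff, NumericVector J_offset,
                  NumericVector s0, NumericVector u0, NumericVector x0,
                  int gain_type, NumericVector gain_pars,
                  double U, double tau_u, double tau_x, double tau_s,
                  double dt, int n_steps, int sample_every, bool noise) {
  const int N = Weff.nrow();
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> phi(N), J(N);
  const double *W = REAL(Weff);
  const double *gp = REAL(gain_pars);
  const bool has_x = tau_x > 0.0;
  const double sqdt = std::sqrt(dt);

  int n_samples = n_steps / sample_every + 1;
  NumericVector times(n_samples), center(n_samples), maxrate(n_samples);
  std::vector<double> cosv(N), sinv(N);
  for (int j = 0; j < N; ++j) {
    cosv[j] = std::cos(2.0 * M_PI * j / N);
    sinv[j] = std::sin(2.0 * M_PI * j / N);
  }
  NumericVector phi_final(N);

  int si = 0;
  for (int step = 0; step <= n_steps; ++step) {
    // J = Weff %*% s + offset
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      const double *wrow = W + i;       // column-major: W[i + N*j]
      for (int j = 0; j < N; ++j) acc += wrow[(size_t)N * j] * s[j];
      J[i] = acc + J_offset[i];
    }
    double re = 0.0, im = 0.0, mx = 0.0;
    for (int i = 0; i < N; ++i) {
      phi[i] = eval_gain(J[i], gain_type, gp);
      re += phi[i] * cosv[i];
      im += phi[i] * sinv[i];
      if (phi[i] > mx) mx = phi[i];
    }
    if (step % sample_every == 0) {
      times[si] = step * dt;
      double ang = std::atan2(im, re) - M_PI;
      ang = ang - 2.0 * M_PI * std::floor((ang + M_PI) / (2.0 * M_PI));
      center[si] = ang;
      maxrate[si] = mx;
      ++si;
    }
    if (step == n_steps) break;
    for (int i = 0; i < N; ++i) {
      double z = noise ? norm_rand() : 0.0;
      double nz = std::sqrt(phi[i] > 0.0 ? phi[i] : 0.0) * sqdt * z;
      double ux = u[i] * x[i];
      double ds = dt * (-s[i] / tau_s + ux * phi[i]) + ux * nz;
      double du = dt * (-(u[i] - U) / tau_u + U * (1.0 - u[i]) * phi[i]) +
        U * (1.0 - u[i]) * nz;
      double dx = has_x ?
        dt * (-(x[i] - 1.0) / tau_x - ux * phi[i]) - ux * nz : 0.0;
      s[i] += ds; u[i] += du; x[i] += dx;
      if (!std::isfinite(s[i]))
        stop("rate simulation diverged at step %d", step);
    }
  }
  for (int i = 0; i < N; ++i) phi_final[i] = phi[i];
  return List::create(_["times"] = times, _["center"] = center,
                      _["maxrate"] = maxrate, _["phi_final"] = phi_final);
}

// Clock-driven conductance-based LIF network with spike-based facilitation
// and depression on the recurrent excitatory connections. Uniform all-to-all
// inhibitory coupling enters through population traces; external drive is an
// independent Poisson source per neuron. Stimulus blocks add Poisson input
// onto the external conductance of a target subset, scaled by `weight`.
// [[Rcpp::export]]
List spiking_cpp(List cfg) {
  const int NE = as<int>(cfg["N_E"]), NI = as<int>(cfg["N_I"]);
  const double dt = as<double>(cfg["dt"]), T = as<double>(cfg["T"]);
  // voltages (mV), conductances (nS), capacitances (nF), times (s)
  const double VL = as<double>(cfg["V_L"]), VE = as<double>(cfg["V_E"]),
    VI = as<double>(cfg["V_I"]), Vthr = as<double>(cfg["V_thr"]),
    Vres = as<double>(cfg["V_res"]);
  const double CmE = as<double>(cfg["Cm_E"]), CmI = as<double>(cfg["Cm_I"]);
  const double gLE = as<double>(cfg["gL_E"]), gLI = as<double>(cfg["gL_I"]);
  const double trefE = as<double>(cfg["tau_ref_E"]),
    trefI = as<double>(cfg["tau_ref_I"]);
  const double tau_ext = as<double>(cfg["tau_ext"]),
    tau_E = as<double>(cfg["tau_E"]), tau_I = as<double>(cfg["tau_I"]);
  const double gextE = as<double>(cfg["g_ext_E"]),
    gextI = as<double>(cfg["g_ext_I"]);
  const double gEE = as<double>(cfg["g_EE"]), gEI = as<double>(cfg["g_EI"]),
    gIE = as<double>(cfg["g_IE"]), gII = as<double>(cfg["g_II"]);
  const double rate_ext = as<double>(cfg["rate_ext"]); // N_ext * nu_ext (Hz)
  const double U = as<double>(cfg["U"]), tau_u = as<double>(cfg["tau_u"]),
    tau_x = as<double>(cfg["tau_x"]);
  const bool stp_frozen = as<bool>(cfg["stp_frozen"]);
  NumericMatrix WEE = as<NumericMatrix>(cfg["W_EE"]); // NE x NE
  NumericVector dL = as<NumericVector>(cfg["delta_L"]); // NE
  // stimulus blocks: matrix with columns t_on, t_off, rate (Hz), weight
  NumericMatrix stim = as<NumericMatrix>(cfg["stim"]);
  LogicalMatrix stim_target = as<LogicalMatrix>(cfg["stim_target"]); // NE x nstim
  // mean-field initial values of the synaptic traces (basal state)
  NumericVector init_sj = as<NumericVector>(cfg["init_sj"]);
  NumericVector init_uj = as<NumericVector>(cfg["init_uj"]);
  NumericVector init_xj = as<NumericVector>(cfg["init_xj"]);
  const double init_sIE = as<double>(cfg["init_sIE"]),
    init_sII = as<double>(cfg["init_sII"]),
    init_sEI = as<double>(cfg["init_sEI"]);

  const int n_steps = (int)std::lround(T / dt);
  const double dEx = std::exp(-dt / tau_ext), dE = std::exp(-dt / tau_E),
    dI = std::exp(-dt / tau_I);
  const double du_f = std::exp(-dt / tau_u);
  const double dx_f = tau_x > 0 ? std::exp(-dt / tau_x) : 0.0;

  std::vector<double> VEv(NE), VIv(NI);
  for (int i = 0; i < NE; ++i) VEv[i] = Vres + (Vthr - Vres) * unif_rand();
  for (int i = 0; i < NI; ++i) VIv[i] = Vres + (Vthr - Vres) * unif_rand();
  std::vector<double> sext_E(NE, rate_ext * tau_ext),
    sext_I(NI, rate_ext * tau_ext);
  std::vector<double> sj(init_sj.begin(), init_sj.end());
  std::vector<double> uj(init_uj.begin(), init_uj.end());
  std::vector<double> xj(init_xj.begin(), init_xj.end());
  double sIE = init_sIE, sII = init_sII, sEI = init_sEI;
  std::vector<double> refr_E(NE, -1.0), refr_I(NI, -1.0);
  std::vector<int> spk_n; std::vector<double> spk_t;
  std::vector<int> spk_nI; std::vector<double> spk_tI;
  const double *W = REAL(WEE);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // conductance decays
    for (int i = 0; i < NE; ++i) sext_E[i] *= dEx;
    for (int i = 0; i < NI; ++i) sext_I[i] *= dEx;
    for (int j = 0; j < NE; ++j) {
      sj[j] *= dE;
      if (!stp_frozen) {
        uj[j] = U + (uj[j] - U) * du_f;
        xj[j] = tau_x > 0 ? 1.0 + (xj[j] - 1.0) * dx_f : 1.0;
      }
    }
    sIE *= dE; sII *= dI; sEI *= dI;
    // external Poisson arrivals
    for (int i = 0; i < NE; ++i) {
      int k = (int)R::rpois(rate_ext * dt);
      if (k > 0) sext_E[i] += k;
    }
    for (int i = 0; i < NI; ++i) {
      int k = (int)R::rpois(rate_ext * dt);
      if (k > 0) sext_I[i] += k;
    }
    // stimulus blocks
    for (int b = 0; b < stim.nrow(); ++b) {
      if (t >= stim(b, 0) && t < stim(b, 1)) {
        double lam = stim(b, 2) * dt;
        double wgt = stim(b, 3);
        for (int i = 0; i < NE; ++i) if (stim_target(i, b)) {
          int k = (int)R::rpois(lam);
          if (k > 0) sext_E[i] += wgt * k;
        }
      }
    }
    // voltage integration: excitatory population
    for (int i = 0; i < NE; ++i) {
      if (t < refr_E[i]) { VEv[i] = Vres; continue; }
      double sEEi = 0.0;
      const double *wrow = W + i;
      for (int j = 0; j < NE; ++j) sEEi += wrow[(size_t)NE * j] * sj[j];
      double V = VEv[i];
      // exponential-Euler: conductances held over the step
      double gtot = gLE + gextE * sext_E[i] + gEI * sEI + gEE * sEEi;
      double Veff = (gLE * (VL + dL[i]) + gextE * sext_E[i] * VE +
                     gEI * sEI * VI + gEE * sEEi * VE) / gtot;
      V = Veff + (V - Veff) * std::exp(-gtot * dt / CmE);
      if (V >= Vthr) {
        spk_n.push_back(i + 1); spk_t.push_back(t + dt);
        refr_E[i] = t + dt + trefE;
        V = Vres;
        // outgoing synapses: release with pre-spike values, then update
        double rel = uj[i] * xj[i];
        if (stp_frozen) rel = U;
        sj[i] += rel;
        if (!stp_frozen) {
          double u_pre = uj[i];
          uj[i] = u_pre + U * (1.0 - u_pre);
          xj[i] = xj[i] - xj[i] * u_pre;
        }
        sIE += 1.0;
      }
      VEv[i] = V;
    }
    // inhibitory population
    for (int i = 0; i < NI; ++i) {
      if (t < refr_I[i]) { VIv[i] = Vres; continue; }
      double V = VIv[i];
      double gtot = gLI + gextI * sext_I[i] + gII * sII + gIE * sIE;
      double Veff = (gLI * VL + gextI * sext_I[i] * VE +
                     gII * sII * VI + gIE * sIE * VE) / gtot;
      V = Veff + (V - Veff) * std::exp(-gtot * dt / CmI);
      if (V >= Vthr) {
        spk_nI.push_back(i + 1); spk_tI.push_back(t + dt);
        refr_I[i] = t + dt + trefI;
        V = Vres;
        sII += 1.0; sEI += 1.0;
      }
      VIv[i] = V;
    }
  }
  return List::create(
    _["spikes_E"] = DataFrame::create(_["neuron"] = wrap(spk_n),
                                      _["t"] = wrap(spk_t)),
    _["spikes_I"] = DataFrame::create(_["neuron"] = wrap(spk_nI),
                                      _["t"] = wrap(spk_tI)));
}

// Monte-Carlo oracle for the diffusion-approximation rate formula: a single
// conductance LIF neuron driven by Poisson external input through an
// exponential synapse, with constant recurrent and inhibitory conductances.
// [[Rcpp::export]]
double mc_lif_rate_cpp(double Cm, double gL, double VL, double VE, double VI,
                       double Vthr, double Vres, double tau_ref,
                       double tau_ext, double g_ext, double rate_ext,
                       double gE_const, double gI_const,
                       double T, double dt) {
  double V = VL, sext = rate_ext * tau_ext;
  const double dEx = std::exp(-dt / tau_ext);
  double refr_until = -1.0;
  long nspk = 0;
  const int n_steps = (int)std::lround(T / dt);
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    sext *= dEx;
    int k = (int)R::rpois(rate_ext * dt);
    if (k > 0) sext += k;
    if (t < refr_until) { V = Vres; continue; }
    double gtot = gL + g_ext * sext + gI_const + gE_const;
    double Veff = (gL * VL + g_ext * sext * VE + gI_const * VI +
                   gE_const * VE) / gtot;
    V = Veff + (V - Veff) * std::exp(-gtot * dt / Cm);
    if (V >= Vthr) {
      ++nspk;
      refr_until = t + dt + tau_ref;
      V = Vres;
    }
  }
  return (double)nspk / T;
}
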