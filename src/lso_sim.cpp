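// Forward-Euler integration core for the six LSO integrate-and-fire models.
//
// Units throughout: mV, ms, nS, pF, pA (so C*dV/dt with C in pF and t in ms
// gives current in pA, and g*(E-V) with g in nS gives pA).
//
// Synaptic alpha-function conductances and the biexponential spike-mimicking
// current are propagated with exact exponential recursions, so per-step cost
// is O(1) regardless of the input spike count and the sampled values agree
// with the direct kernel sums to machine precision for grid-aligned spikes.

#include <Rcpp.h>
using namespace Rcpp;

// Exact recursion for a sum of alpha kernels A*(dt/tau)*exp(1-dt/tau).
// State: p = sum exp(-(t-ts)/tau), q = sum ((t-ts)/tau)*exp(-(t-ts)/tau).
// Conductance at t is A*e*q.
struct AlphaState {
  double p, q, rho, dt_tau, amp;
  void init(double A, double tau, double dt) {
    p = 0.0; q = 0.0;
    rho = std::exp(-dt / tau);
    dt_tau = dt / tau;
    amp = A * M_E;
  }
  inline double g() const { return amp * q; }
  inline void advance() {
    q = rho * (q + dt_tau * p);
    p = rho * p;
  }
  inline void impulse() { p += 1.0; }
};

// [[Rcpp::export]]
NumericVector cpp_alpha_trace(NumericVector spike_times, double A, double tau,
                              double dt, int n_samples) {
  if (dt <= 0) stop("dt must be positive");
  AlphaState st;
  st.init(A, tau, dt);
  int n_spk = spike_times.size();
  std::vector<long> idx(n_spk);
  for (int i = 0; i < n_spk; ++i) idx[i] = (long)std::llround(spike_times[i] / dt);
  std::sort(idx.begin(), idx.end());
  NumericVector out(n_samples);
  int ip = 0;
  for (int k = 0; k < n_samples; ++k) {
    while (ip < n_spk && idx[ip] == (long)k) { st.impulse(); ++ip; }
    out[k] = st.g();
    st.advance();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_lso(double C, double gL, double EL,
                      double gK, double EK,
                      double gT, double VT, double KT,
                      double Vth, double Vref, double Tref,
                      double A1, double A2, double tau1, double tau2,
                      bool use_klva, bool use_exp, bool use_spk,
                      NumericVector exc_times, NumericVector inh_times,
                      double AE, double tauE, double EE,
                      double AI, double tauI, double EI,
                      double dt, int n_steps,
                      double v0, double d0,
                      NumericVector i_inj,
                      bool spiking, bool record,
                      double exp_clip) {
  if (dt <= 0) stop("dt must be positive");
  if (n_steps < 1) stop("n_steps must be >= 1");

  AlphaState synE, synI;
  synE.init(AE, tauE, dt);
  synI.init(AI, tauI, dt);

  // spike-mimicking current accumulators: s1 = sum exp(-(t-s)/tau1), etc.
  double s1 = 0.0, s2 = 0.0;
  const double rho1 = (tau1 > 0) ? std::exp(-dt / tau1) : 0.0;
  const double rho2 = (tau2 > 0) ? std::exp(-dt / tau2) : 0.0;

  // grid indices of input spikes (sorted)
  const int nE = exc_times.size(), nI = inh_times.size();
  std::vector<long> idxE(nE), idxI(nI);
  for (int i = 0; i < nE; ++i) idxE[i] = (long)std::llround(exc_times[i] / dt);
  for (int i = 0; i < nI; ++i) idxI[i] = (long)std::llround(inh_times[i] / dt);
  std::sort(idxE.begin(), idxE.end());
  std::sort(idxI.begin(), idxI.end());

  const int n_inj = i_inj.size();

  double V = v0, d = d0;
  double refrac_until = -1.0;
  const bool resets = !use_spk;  // PLk/PEx/ALk/AEx reset and clamp; PSp/ASp do not

  std::vector<double> spikes;
  NumericVector v_out = record ? NumericVector(n_steps + 1) : NumericVector(0);
  NumericVector d_out = (record && use_klva) ? NumericVector(n_steps + 1)
                                             : NumericVector(0);
  if (record) {
    v_out[0] = V;
    if (use_klva) d_out[0] = d;
  }

  int ipE = 0, ipI = 0;
  const double dt_over_C = dt / C;

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    while (ipE < nE && idxE[ipE] <= (long)k) { synE.impulse(); ++ipE; }
    while (ipI < nI && idxI[ipI] <= (long)k) { synI.impulse(); ++ipI; }

    const bool clamped = resets && (t < refrac_until);

    // KLVA gating always integrates (at the clamped potential when clamped)
    double alpha = 0.0, beta = 0.0;
    if (use_klva) {
      const double ex = std::exp((V + 50.0) / 16.0);
      alpha = 0.5 * ex;
      beta = 0.5 / ex;
    }

    if (!clamped) {
      double Iall = synE.g() * (EE - V) + synI.g() * (EI - V) + gL * (EL - V);
      if (use_klva) Iall += gK * d * (EK - V);
      if (use_exp) {
        double x = (V - VT) / KT;
        if (x > exp_clip) x = exp_clip;
        Iall += gT * KT * std::exp(x);
      }
      if (use_spk) Iall += A1 * s1 - A2 * s2;
      if (n_inj == 1) Iall += i_inj[0];
      else if (n_inj > 1) Iall += i_inj[k];
      V += dt_over_C * Iall;
    }
    if (use_klva) {
      d += dt * (alpha * (1.0 - d) - beta * d);
      if (d < 0.0) d = 0.0;
      else if (d > 1.0) d = 1.0;
    }
    synE.advance();
    synI.advance();
    s1 *= rho1;
    s2 *= rho2;

    if (!std::isfinite(V))
      stop("membrane potential became non-finite at t = %f ms (dt = %f ms)",
           t + dt, dt);

    const double t_next = (k + 1) * dt;
    if (spiking && V >= Vth && t_next >= refrac_until && !clamped) {
      spikes.push_back(t_next);
      refrac_until = t_next + Tref;
      if (resets) V = Vref;
      else { s1 += 1.0; s2 += 1.0; }
    }

    if (record) {
      v_out[k + 1] = V;
      if (use_klva) d_out[k + 1] = d;
    }
  }

  return List::create(_["spike_times"] = wrap(spikes),
                      _["v"] = v_out,
                      _["d"] = d_out,
                      _["v_final"] = V,
                      _["d_final"] = d);
}
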