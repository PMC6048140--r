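// Compiled integrators: single AdEx neuron, single synaptic gate, and the
// full recurrent network. All use second-order Runge-Kutta (Heun) with
// impulsive events (spike deliveries) applied at step boundaries.
//
// Units: pA, mV, nS, pF, ms throughout (nS * mV = pA).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct AdExP {
  double C, gL, VL, DeltaT, VT, Vreset, Vpeak, tau_u, a_u, b_u, t_ref;
};

static AdExP as_params(const List& p) {
  AdExP q;
  q.C = p["C"]; q.gL = p["g_L"]; q.VL = p["V_L"]; q.DeltaT = p["Delta_T"];
  q.VT = p["V_T"]; q.Vreset = p["V_reset"]; q.Vpeak = p["V_peak"];
  q.tau_u = p["tau_u"]; q.a_u = p["a_u"]; q.b_u = p["b_u"];
  q.t_ref = p["t_ref"];
  return q;
}

// Hot kernels: weighted sums of weight-matrix columns over presynaptic
// gates, both Runge-Kutta stages accumulated in one pass over the matrix.
// Function multiversioning lets the runtime pick an AVX2/FMA clone when the
// host supports it while keeping a portable baseline binary.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define UPSTATES_CLONES \
  __attribute__((optimize("O3"), target_clones("arch=haswell", "default")))
#else
#define UPSTATES_CLONES
#endif

UPSTATES_CLONES
static void col_axpy2(int N, int ncol, const float* __restrict__ J,
                      const float* __restrict__ w1v,
                      const float* __restrict__ w2v,
                      float* __restrict__ a1, float* __restrict__ a2) {
  for (int j = 0; j < ncol; ++j) {
    const float w1 = w1v[j], w2 = w2v[j];
    if (w1 < 1e-5f && w2 < 1e-5f) continue;
    const float* __restrict__ col = J + (size_t)j * N;
    for (int i = 0; i < N; ++i) {
      const float c = col[i];
      a1[i] += c * w1;
      a2[i] += c * w2;
    }
  }
}

UPSTATES_CLONES
static void col_axpy4(int N, int ncol, const float* __restrict__ J,
                      const float* __restrict__ w1v,
                      const float* __restrict__ w2v,
                      const float* __restrict__ w3v,
                      const float* __restrict__ w4v,
                      float* __restrict__ a1, float* __restrict__ a2,
                      float* __restrict__ a3, float* __restrict__ a4) {
  for (int j = 0; j < ncol; ++j) {
    const float w1 = w1v[j], w2 = w2v[j], w3 = w3v[j], w4 = w4v[j];
    if (w1 < 1e-5f && w2 < 1e-5f && w3 < 1e-5f && w4 < 1e-5f) continue;
    const float* __restrict__ col = J + (size_t)j * N;
    for (int i = 0; i < N; ++i) {
      const float c = col[i];
      a1[i] += c * w1;
      a2[i] += c * w2;
      a3[i] += c * w3;
      a4[i] += c * w4;
    }
  }
}

static inline double refr(double dt_since, double t_ref) {
  double r = dt_since / t_ref;
  if (r <= 0.0) return 0.0;
  if (r > 3.0) return 1.0;
  return 1.0 - std::exp(-std::pow(r, 20.0));
}

static inline double expterm(double V, const AdExP& p) {
  double e = (V - p.VT) / p.DeltaT;
  if (e > 30.0) e = 30.0;
  return p.gL * p.DeltaT * std::exp(e);
}

// one Heun step of a single neuron under total current I; returns spike
// flag. The refractory factor suppresses the spike-generation term for
// ~t_ref after a spike; spike detection is additionally disabled in that
// window so inter-spike intervals are never shorter than t_ref.
static inline bool neuron_step(double& V, double& u, double& tsp,
                               double I, double t, double dt,
                               const AdExP& p, double& t_spike) {
  // the adaptation driver sees V clipped at V_peak: past the detection
  // ceiling the trajectory is a divergence artifact, not a real potential
  double R1 = refr(t - tsp, p.t_ref);
  double dV1 = (-p.gL * (V - p.VL) + expterm(V, p) * R1 - u + I) / p.C;
  double du1 = (-u + p.a_u * (std::min(V, p.Vpeak) - p.VL)) / p.tau_u;
  double V1 = V + dt * dV1, u1 = u + dt * du1;
  double R2 = refr(t + dt - tsp, p.t_ref);
  double dV2 = (-p.gL * (V1 - p.VL) + expterm(V1, p) * R2 - u1 + I) / p.C;
  double du2 = (-u1 + p.a_u * (std::min(V1, p.Vpeak) - p.VL)) / p.tau_u;
  double Vn = V + dt / 2.0 * (dV1 + dV2);
  double un = u + dt / 2.0 * (du1 + du2);
  bool spike = false;
  if (Vn >= p.Vpeak) {
    if (t - tsp >= p.t_ref) {
      double frac = (Vn > V) ? (p.Vpeak - V) / (Vn - V) : 1.0;
      if (frac > 1.0) frac = 1.0;
      if (frac < 0.0) frac = 0.0;
      t_spike = t + dt * frac;
      tsp = t_spike;
      Vn = p.Vreset;
      un += p.b_u;
      spike = true;
    } else {
      Vn = p.Vpeak;  // held at the ceiling until the refractory gate opens
    }
  }
  V = Vn; u = un;
  return spike;
}

// [[Rcpp::export]]
NumericVector simulate_neuron_cpp(List params, double I, double T, double dt) {
  AdExP p = as_params(params);
  double V = p.VL, u = 0.0, tsp = -1e30, ts;
  std::vector<double> spikes;
  long nsteps = (long)std::ceil(T / dt);
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    if (neuron_step(V, u, tsp, I, t, dt, p, ts)) spikes.push_back(ts);
  }
  return wrap(spikes);
}

// [[Rcpp::export]]
List simulate_neuron_trace_cpp(List params, double I, double T, double dt) {
  AdExP p = as_params(params);
  double V = p.VL, u = 0.0, tsp = -1e30, ts;
  long nsteps = (long)std::ceil(T / dt);
  std::vector<double> spikes;
  NumericVector time(nsteps), Vout(nsteps);
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    if (neuron_step(V, u, tsp, I, t, dt, p, ts)) spikes.push_back(ts);
    time[k] = t + dt;
    Vout[k] = V;
  }
  return List::create(_["spikes"] = wrap(spikes), _["time"] = time,
                      _["V"] = Vout);
}

// Second-order gating kinetics of a single synapse driven by a list of
// (already delayed) presynaptic spike delivery times.
// [[Rcpp::export]]
List simulate_gating_cpp(double tau_up, double tau_dn,
                         NumericVector deliveries, double T, double dt,
                         bool keep_trace = false, double kick = 1.0,
                         bool saturating = true) {
  double x = 0.0, s = 0.0;
  long nsteps = (long)std::ceil(T / dt);
  R_xlen_t ev = 0;
  double sum_s = 0.0, smin = 0.0, smax = 0.0;
  NumericVector trace(keep_trace ? nsteps : 0);
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    while (ev < deliveries.size() && deliveries[ev] <= t) {
      if (saturating) s = 1.0; else x += kick / tau_up;
      ++ev;
    }
    double dx1 = -x / tau_up;
    double ds1 = x * (1.0 - s) - s / tau_dn;
    double x1 = x + dt * dx1, s1 = s + dt * ds1;
    double dx2 = -x1 / tau_up;
    double ds2 = x1 * (1.0 - s1) - s1 / tau_dn;
    x += dt / 2.0 * (dx1 + dx2);
    s += dt / 2.0 * (ds1 + ds2);
    if (s < 0.0) s = 0.0;
    if (s > 1.0) s = 1.0;
    sum_s += s;
    if (s < smin) smin = s;
    if (s > smax) smax = s;
    if (keep_trace) trace[k] = s;
  }
  return List::create(_["mean_s"] = sum_s / nsteps, _["min_s"] = smin,
                      _["max_s"] = smax, _["s"] = trace);
}

// Full network simulation.
//
// JE: (N x N_E) weights of excitatory presynaptic connections (rows:
//     postsynaptic E then I); JI: (N x N_I) inhibitory presynaptic weights.
// Receptor groups share reversal potential and conductance within
// {AMPA, NMDA} and {GABA-A fast, GABA-A slow} so their gates are combined
// before the weight sums (validated on the R side).
// [[Rcpp::export]]
List run_network_cpp(List params, NumericMatrix JE, NumericMatrix JI,
                     NumericVector J_input, List receptors,
                     double gamma_E, double gamma_I,
                     double input_rate, double input_amp,
                     double tau_in_up, double tau_in_dn,
                     double tau_axon, double noise_sd,
                     bool gate_saturating, double gate_charge,
                     double T, double dt,
                     IntegerVector trace_ids, double trace_dt) {
  AdExP p = as_params(params);
  const int NE = JE.ncol(), NI = JI.ncol(), N = JE.nrow();
  if (JI.nrow() != N || N != NE + NI) stop("weight block dimensions mismatch");
  NumericVector tau_up = receptors["tau_up"], tau_dn = receptors["tau_dn"],
                V_R = receptors["V_R"], gcond = receptors["g"];
  // receptor order: AMPA, NMDA, GABA-A fast, GABA-A slow, GABA-B
  const double gA = gcond[0], gN = gcond[1], gGf = gcond[2], gGs = gcond[3],
               gGb = gcond[4];
  const double VRe = V_R[0], VRga = V_R[2], VRgb = V_R[4];

  std::vector<float> fJE(JE.begin(), JE.end());
  std::vector<float> fJI(JI.begin(), JI.end());

  // state
  std::vector<double> V(N, p.VL), u(N, 0.0), tsp(N, -1e30);
  std::vector<double> xA(NE, 0), sA(NE, 0), xN(NE, 0), sN(NE, 0);
  std::vector<double> xGf(NI, 0), sGf(NI, 0), xGs(NI, 0), sGs(NI, 0),
                      xGb(NI, 0), sGb(NI, 0);
  std::vector<double> xin(NE, 0), sin_(NE, 0), next_in(NE, 0);

  const long nsteps = (long)std::ceil(T / dt);
  const int delay_steps = (int)std::lround(tau_axon / dt);
  const int bufsize = delay_steps + 4;
  std::vector< std::vector<int> > ring(bufsize);

  const double isi_scale = (input_rate > 0) ? 1000.0 / input_rate : 0.0;
  for (int i = 0; i < NE; ++i) {
    next_in[i] = (input_rate > 0) ? tau_axon + exp_rand() * isi_scale : 1e300;
  }

  // stage weight vectors and accumulators
  std::vector<float> wE1(NE), wE2(NE), wGA1(NI), wGA2(NI), wGB1(NI), wGB2(NI);
  std::vector<float> accE1(N), accE2(N), accGA1(N), accGA2(N), accGB1(N),
                     accGB2(N);
  std::vector<double> sin1(NE), sin2(NE), eta;
  if (noise_sd > 0) eta.resize(N);

  std::vector<int> spike_id;  std::vector<double> spike_t;
  const int ntr = trace_ids.size();
  const long tr_stride = std::max(1L, (long)std::lround(trace_dt / dt));
  const long ntr_samples = ntr > 0 ? nsteps / tr_stride : 0;
  NumericMatrix traces(ntr_samples, ntr);
  NumericVector trace_times(ntr_samples);
  long tr_row = 0;

  // gate Heun update helper (per array); also fills stage-1/2 s values
  auto gate_stages = [dt](std::vector<double>& x, std::vector<double>& s,
                          double tup, double tdn, int n,
                          double* s1out, double* s2out) {
    for (int j = 0; j < n; ++j) {
      double dx1 = -x[j] / tup;
      double ds1 = x[j] * (1.0 - s[j]) - s[j] / tdn;
      double x1 = x[j] + dt * dx1, s1 = s[j] + dt * ds1;
      double dx2 = -x1 / tup;
      double ds2 = x1 * (1.0 - s1) - s1 / tdn;
      if (s1out) s1out[j] = s[j];
      if (s2out) s2out[j] = s1;
      x[j] += dt / 2.0 * (dx1 + dx2);
      s[j] += dt / 2.0 * (ds1 + ds2);
      if (s[j] < 1e-30) s[j] = 0.0; else if (s[j] > 1.0) s[j] = 1.0;
      if (x[j] < 1e-30) x[j] = 0.0;  // flush decayed gates (avoid subnormals)
    }
  };

  std::vector<double> sA1(NE), sA2(NE), sN1(NE), sN2(NE);
  std::vector<double> sGf1(NI), sGf2(NI), sGs1(NI), sGs2(NI), sGb1(NI),
                      sGb2(NI);

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    // 1. deliver recurrent spikes scheduled for this step
    std::vector<int>& due = ring[k % bufsize];
    for (size_t m = 0; m < due.size(); ++m) {
      int id = due[m];
      if (id < NE) {
        if (gate_saturating) { sA[id] = 1.0; sN[id] = 1.0; }
        else { xA[id] += gate_charge / tau_up[0];
               xN[id] += gate_charge / tau_up[1]; }
      } else {
        int j = id - NE;
        if (gate_saturating) { sGf[j] = 1.0; sGs[j] = 1.0; sGb[j] = 1.0; }
        else { xGf[j] += gate_charge / tau_up[2];
               xGs[j] += gate_charge / tau_up[3];
               xGb[j] += gate_charge / tau_up[4]; }
      }
    }
    due.clear();
    // afferent Poisson deliveries (E cells only)
    if (input_rate > 0) {
      for (int i = 0; i < NE; ++i) {
        while (next_in[i] <= t) {
          if (gate_saturating) sin_[i] = 1.0;
          else xin[i] += gate_charge / tau_in_up;
          next_in[i] += exp_rand() * isi_scale;
        }
      }
    }
    // 2. advance gates, keeping stage values
    gate_stages(xA, sA, tau_up[0], tau_dn[0], NE, sA1.data(), sA2.data());
    gate_stages(xN, sN, tau_up[1], tau_dn[1], NE, sN1.data(), sN2.data());
    gate_stages(xGf, sGf, tau_up[2], tau_dn[2], NI, sGf1.data(), sGf2.data());
    gate_stages(xGs, sGs, tau_up[3], tau_dn[3], NI, sGs1.data(), sGs2.data());
    gate_stages(xGb, sGb, tau_up[4], tau_dn[4], NI, sGb1.data(), sGb2.data());
    gate_stages(xin, sin_, tau_in_up, tau_in_dn, NE, sin1.data(), sin2.data());
    for (int j = 0; j < NE; ++j) {
      wE1[j] = (float)(gA * sA1[j] + gN * sN1[j]);
      wE2[j] = (float)(gA * sA2[j] + gN * sN2[j]);
    }
    for (int j = 0; j < NI; ++j) {
      wGA1[j] = (float)(gGf * sGf1[j] + gGs * sGs1[j]);
      wGA2[j] = (float)(gGf * sGf2[j] + gGs * sGs2[j]);
      wGB1[j] = (float)(gGb * sGb1[j]);
      wGB2[j] = (float)(gGb * sGb2[j]);
    }
    // 3. weighted sums over presynaptic gates (the cost driver)
    std::fill(accE1.begin(), accE1.end(), 0.0f);
    std::fill(accE2.begin(), accE2.end(), 0.0f);
    std::fill(accGA1.begin(), accGA1.end(), 0.0f);
    std::fill(accGA2.begin(), accGA2.end(), 0.0f);
    std::fill(accGB1.begin(), accGB1.end(), 0.0f);
    std::fill(accGB2.begin(), accGB2.end(), 0.0f);
    col_axpy2(N, NE, fJE.data(), wE1.data(), wE2.data(),
              accE1.data(), accE2.data());
    col_axpy4(N, NI, fJI.data(), wGA1.data(), wGA2.data(), wGB1.data(),
              wGB2.data(), accGA1.data(), accGA2.data(), accGB1.data(),
              accGB2.data());
    if (noise_sd > 0) {
      // white-current noise, parameterized as the s.d. of its average over
      // a 1 ms window so its effect is invariant to the integration step
      const double amp = noise_sd * std::sqrt(1.0 / dt);
      for (int i = 0; i < N; ++i) eta[i] = amp * norm_rand();
    }
    // 4. neuron update (Heun, synaptic current evaluated at both stages)
    for (int i = 0; i < N; ++i) {
      double Iin1 = 0.0, Iin2 = 0.0;
      if (i < NE) {
        Iin1 = gamma_E * input_amp * J_input[i] * sin1[i];
        Iin2 = gamma_E * input_amp * J_input[i] * sin2[i];
      }
      double nz = (noise_sd > 0) ? eta[i] : 0.0;
      double Vi = V[i], ui = u[i];
      double Isyn1 = gamma_E * accE1[i] * (VRe - Vi) +
                     gamma_I * (accGA1[i] * (VRga - Vi) +
                                accGB1[i] * (VRgb - Vi));
      double R1 = refr(t - tsp[i], p.t_ref);
      double dV1 = (-p.gL * (Vi - p.VL) + expterm(Vi, p) * R1 - ui +
                    Isyn1 + Iin1 + nz) / p.C;
      double du1 = (-ui + p.a_u * (std::min(Vi, p.Vpeak) - p.VL)) / p.tau_u;
      double V1 = Vi + dt * dV1, u1 = ui + dt * du1;
      double Isyn2 = gamma_E * accE2[i] * (VRe - V1) +
                     gamma_I * (accGA2[i] * (VRga - V1) +
                                accGB2[i] * (VRgb - V1));
      double R2 = refr(t + dt - tsp[i], p.t_ref);
      double dV2 = (-p.gL * (V1 - p.VL) + expterm(V1, p) * R2 - u1 +
                    Isyn2 + Iin2 + nz) / p.C;
      double du2 = (-u1 + p.a_u * (std::min(V1, p.Vpeak) - p.VL)) / p.tau_u;
      double Vn = Vi + dt / 2.0 * (dV1 + dV2);
      double un = ui + dt / 2.0 * (du1 + du2);
      if (std::isnan(Vn) || !std::isfinite(un)) {
        stop("integration failure at t = %f ms (neuron %d)", t, i + 1);
      }
      if (Vn >= p.Vpeak) {
        if (t - tsp[i] >= p.t_ref) {
          double frac = (Vn > Vi) ? (p.Vpeak - Vi) / (Vn - Vi) : 1.0;
          if (frac > 1.0) frac = 1.0;
          if (frac < 0.0) frac = 0.0;
          double tstar = t + dt * frac;
          spike_id.push_back(i + 1);
          spike_t.push_back(tstar);
          tsp[i] = tstar;
          Vn = p.Vreset;
          un += p.b_u;
          long ks = (long)std::ceil((tstar + tau_axon) / dt);
          if (ks <= k) ks = k + 1;
          ring[ks % bufsize].push_back(i);
        } else {
          Vn = p.Vpeak;  // held at ceiling until the refractory gate opens
        }
      }
      V[i] = Vn; u[i] = un;
    }
    // 5. traces
    if (ntr > 0 && (k + 1) % tr_stride == 0 && tr_row < ntr_samples) {
      for (int c = 0; c < ntr; ++c) traces(tr_row, c) = V[trace_ids[c] - 1];
      trace_times[tr_row] = t + dt;
      ++tr_row;
    }
  }
  return List::create(_["spike_id"] = wrap(spike_id),
                      _["spike_t"] = wrap(spike_t),
                      _["traces"] = traces,
                      _["trace_times"] = trace_times,
                      _["N_E"] = NE, _["N_I"] = NI);
}
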