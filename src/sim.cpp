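// Fixed-step integrator for a single-compartment fusiform-cell model with
// leak, Boltzmann-gated KCNQ (first-order kinetics), HCN, an optional extra
// linear conductance, and an exponential integrate-and-fire spike mechanism.
// Units: mV, ms, pA, pF, nS (pA/pF = mV/ms; nS * mV = pA).
#include <Rcpp.h>
using namespace Rcpp;

struct Cell {
  double Cm, gL, EL;
  double gK, VhK, kK, tauK, EK;
  double gH, VhH, kH, tauH, EH;
  double gX, EX;                       // extra linear conductance (e.g. Kir-like)
  bool spike_on;
  double DeltaT, VT, Vcut, Vreset, Vpeak, t_ref;
};

static Cell unpack(const NumericVector &p) {
  Cell c;
  c.Cm = p["Cm"];   c.gL = p["gL"];   c.EL = p["EL"];
  c.gK = p["gK"];   c.VhK = p["VhK"]; c.kK = p["kK"];
  c.tauK = p["tauK"]; c.EK = p["EK"];
  c.gH = p["gH"];   c.VhH = p["VhH"]; c.kH = p["kH"];
  c.tauH = p["tauH"]; c.EH = p["EH"];
  c.gX = p["gX"];   c.EX = p["EX"];
  c.spike_on = p["spike_on"] > 0.5;
  c.DeltaT = p["DeltaT"]; c.VT = p["VT"]; c.Vcut = p["Vcut"];
  c.Vreset = p["Vreset"]; c.Vpeak = p["Vpeak"]; c.t_ref = p["t_ref"];
  return c;
}

static inline double minf(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}
static inline double hinf(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp((V - Vh) / k));
}

// [[Rcpp::export]]
List sim_voltage_clamp(NumericVector V_cmd, double dt, NumericVector params,
                       double m0, double h0) {
  Cell c = unpack(params);
  int n = V_cmd.size();
  NumericVector I_total(n), I_k(n), I_h(n), I_leak(n);
  double m = m0, h = h0;
  double aK = std::exp(-dt / c.tauK), aH = std::exp(-dt / c.tauH);
  for (int i = 0; i < n; ++i) {
    double V = V_cmd[i];
    I_leak[i] = c.gL * (V - c.EL) + c.gX * (V - c.EX);
    I_k[i] = c.gK * m * (V - c.EK);
    I_h[i] = c.gH * h * (V - c.EH);
    I_total[i] = I_leak[i] + I_k[i] + I_h[i];
    m = minf(V, c.VhK, c.kK) + (m - minf(V, c.VhK, c.kK)) * aK;
    h = hinf(V, c.VhH, c.kH) + (h - hinf(V, c.VhH, c.kH)) * aH;
    if (!std::isfinite(m) || !std::isfinite(h))
      stop("voltage-clamp integration diverged at step %d", i);
  }
  return List::create(_["I_total"] = I_total, _["I_kcnq"] = I_k,
                      _["I_hcn"] = I_h, _["I_leak"] = I_leak);
}

// [[Rcpp::export]]
List sim_current_clamp(NumericVector I_cmd, double dt, NumericVector params,
                       double V0, double m0, double h0,
                       NumericVector I_noise) {
  Cell c = unpack(params);
  int n = I_cmd.size();
  bool has_noise = I_noise.size() == n;
  NumericVector V(n);
  std::vector<double> spikes;
  double v = V0, m = m0, h = h0;
  double aK = std::exp(-dt / c.tauK), aH = std::exp(-dt / c.tauH);
  int ref_steps = (int)std::ceil(c.t_ref / dt);
  int ref_left = 0;
  for (int i = 0; i < n; ++i) {
    if (ref_left > 0) {
      v = c.Vreset;
      --ref_left;
      V[i] = v;
    } else {
      double I_ion = c.gL * (v - c.EL) + c.gX * (v - c.EX) +
                     c.gK * m * (v - c.EK) + c.gH * h * (v - c.EH);
      double psi = 0.0;
      if (c.spike_on) {
        double arg = (v - c.VT) / c.DeltaT;
        if (arg > 30.0) arg = 30.0;   // clipped: spike fires before this matters
        psi = c.gL * c.DeltaT * std::exp(arg);
      }
      double I_in = I_cmd[i] + (has_noise ? I_noise[i] : 0.0);
      v += dt / c.Cm * (-I_ion + psi + I_in);
      if (c.spike_on && v >= c.Vcut) {
        spikes.push_back(i * dt);
        V[i] = c.Vpeak;
        v = c.Vreset;
        ref_left = ref_steps;
        // gates keep relaxing through the spike below
      } else {
        V[i] = v;
      }
    }
    double mi = minf(v, c.VhK, c.kK), hi = hinf(v, c.VhH, c.kH);
    m = mi + (m - mi) * aK;
    h = hi + (h - hi) * aH;
    if (!std::isfinite(v))
      stop("current-clamp integration diverged at step %d (check conductances/dt)", i);
  }
  return List::create(_["V"] = V, _["spike_times"] = wrap(spikes));
}
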