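#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley squid-axon rate functions at 6.3 C (times in ms, V in mV).
// vtrap-style guards remove the removable singularities.
static inline double alpha_m(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-6) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-6) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// Tabulated steady states and time constants on a 201-point grid spanning
// [-100, 100] mV with linear interpolation, matching the reference
// simulator's default rate-table treatment; outside the grid the exact
// expressions are used.
struct HHTables {
  static const int N = 201;
  double vmin = -100.0, vmax = 100.0, dv;
  double minf[N], mtau[N], hinf[N], htau[N], ninf[N], ntau[N];
  HHTables() {
    dv = (vmax - vmin) / (N - 1);
    for (int i = 0; i < N; ++i) {
      double v = vmin + i * dv;
      double am = alpha_m(v), bm = beta_m(v);
      double ah = alpha_h(v), bh = beta_h(v);
      double an = alpha_n(v), bn = beta_n(v);
      minf[i] = am / (am + bm); mtau[i] = 1.0 / (am + bm);
      hinf[i] = ah / (ah + bh); htau[i] = 1.0 / (ah + bh);
      ninf[i] = an / (an + bn); ntau[i] = 1.0 / (an + bn);
    }
  }
  inline void lookup(double v, double *mi, double *mt, double *hi, double *ht,
                     double *ni, double *nt) const {
    if (v <= vmin || v >= vmax) {
      double am = alpha_m(v), bm = beta_m(v);
      double ah = alpha_h(v), bh = beta_h(v);
      double an = alpha_n(v), bn = beta_n(v);
      *mi = am / (am + bm); *mt = 1.0 / (am + bm);
      *hi = ah / (ah + bh); *ht = 1.0 / (ah + bh);
      *ni = an / (an + bn); *nt = 1.0 / (an + bn);
      return;
    }
    double u = (v - vmin) / dv;
    int i = (int)u;
    double f = u - i;
    *mi = minf[i] + f * (minf[i + 1] - minf[i]);
    *mt = mtau[i] + f * (mtau[i + 1] - mtau[i]);
    *hi = hinf[i] + f * (hinf[i + 1] - hinf[i]);
    *ht = htau[i] + f * (htau[i + 1] - htau[i]);
    *ni = ninf[i] + f * (ninf[i + 1] - ninf[i]);
    *nt = ntau[i] + f * (ntau[i + 1] - ntau[i]);
  }
};

// [[Rcpp::export]]
NumericVector hh_core(double gna, double gk, double gl, double area_cm2,
                      double cm, double ena, double ek, double el,
                      double v_init, double dt, NumericVector istim_nA,
                      bool use_table = true) {
  static HHTables tab;
  int n = istim_nA.size();
  NumericVector out(n);
  double v = v_init;
  double mi, mt, hi, ht, ni, nt;
  // gating initialized at steady state for v_init (exact rates)
  double am = alpha_m(v), bm = beta_m(v);
  double ah = alpha_h(v), bh = beta_h(v);
  double an = alpha_n(v), bn = beta_n(v);
  double m = am / (am + bm), h = ah / (ah + bh), nn = an / (an + bn);
  out[0] = v;
  // conductances in mS/cm2 so that g * mV = uA/cm2 with Cm in uF/cm2
  double GNA = gna * 1e3, GK = gk * 1e3, GL = gl * 1e3;
  for (int i = 0; i + 1 < n; ++i) {
    // staggered scheme: implicit voltage step with frozen conductances,
    // then analytic exponential gating update at the new voltage
    double gNa = GNA * m * m * m * h;
    double gK = GK * nn * nn * nn * nn;
    double I = istim_nA[i + 1] * 1e-3 / area_cm2;  // nA -> uA/cm2
    double a = cm / dt + gNa + gK + GL;
    double b = cm * v / dt + gNa * ena + gK * ek + GL * el + I;
    v = b / a;
    if (use_table) {
      tab.lookup(v, &mi, &mt, &hi, &ht, &ni, &nt);
    } else {
      am = alpha_m(v); bm = beta_m(v);
      ah = alpha_h(v); bh = beta_h(v);
      an = alpha_n(v); bn = beta_n(v);
      mi = am / (am + bm); mt = 1.0 / (am + bm);
      hi = ah / (ah + bh); ht = 1.0 / (ah + bh);
      ni = an / (an + bn); nt = 1.0 / (an + bn);
    }
    m = mi + (m - mi) * std::exp(-dt / mt);
    h = hi + (h - hi) * std::exp(-dt / ht);
    nn = ni + (nn - ni) * std::exp(-dt / nt);
    out[i + 1] = v;
  }
  return out;
}

// Adaptive exponential integrate-and-fire: RK4 on the sub-threshold
// two-variable system, spike when V reaches V_cut = VT + 5*deltaT (crossing
// located by linear interpolation within the step), then reset with
// adaptation increment and an absolute refractory clamp at Vr.
// Units: C nF, gL/a uS, voltages mV, tref/tauw ms, b and I nA.
// [[Rcpp::export]]
List adexp_core(double C, double gL, double EL, double VT, double Vr,
                double tref, double deltaT, double a, double b, double tauw,
                double v_init, double w_init, double dt,
                NumericVector istim_nA) {
  int n = istim_nA.size();
  NumericVector out(n);
  std::vector<double> spikes;
  double vcut = VT + 5.0 * deltaT;
  double xcap = (vcut - VT) / deltaT;  // cap on the exponential argument
  double v = v_init, w = w_init;
  double t_ref_end = -1.0;
  out[0] = v;
  for (int i = 0; i + 1 < n; ++i) {
    double t = i * dt;
    double I = istim_nA[i + 1];
    if (t + dt <= t_ref_end) {            // fully refractory step: V clamped
      // w still relaxes toward a*(Vr - EL) while V is clamped at Vr
      double winf = a * (Vr - EL);
      w = winf + (w - winf) * std::exp(-dt / tauw);
      v = Vr;
      out[i + 1] = v;
      continue;
    }
    double v0 = v, w0 = w;
    auto fV = [&](double V, double W) {
      double x = (V - VT) / deltaT;
      if (x > xcap) x = xcap;
      return (-gL * (V - EL) + gL * deltaT * std::exp(x) - W + I) / C;
    };
    auto fW = [&](double V, double W) { return (a * (V - EL) - W) / tauw; };
    double k1v = fV(v0, w0), k1w = fW(v0, w0);
    double k2v = fV(v0 + dt / 2 * k1v, w0 + dt / 2 * k1w),
           k2w = fW(v0 + dt / 2 * k1v, w0 + dt / 2 * k1w);
    double k3v = fV(v0 + dt / 2 * k2v, w0 + dt / 2 * k2w),
           k3w = fW(v0 + dt / 2 * k2v, w0 + dt / 2 * k2w);
    double k4v = fV(v0 + dt * k3v, w0 + dt * k3w),
           k4w = fW(v0 + dt * k3v, w0 + dt * k3w);
    double vn = v0 + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v);
    double wn = w0 + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w);
    if (vn >= vcut) {
      double frac = (vcut - v0) / (vn - v0);
      if (!(frac > 0.0 && frac <= 1.0)) frac = 1.0;
      double t_sp = t + frac * dt;
      spikes.push_back(t_sp);
      out[i + 1] = vcut;                  // spike drawn as one sample at V_cut
      v = Vr;
      w = wn + b;
      t_ref_end = t_sp + tref;
    } else {
      v = vn;
      w = wn;
      out[i + 1] = v;
    }
  }
  return List::create(_["v"] = out, _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}
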