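#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squid-axon gating rate constants (rest near -65 mV convention).
// Removable singularities replaced by analytic limits within 1e-7 of the
// singular potential, matching the R-level rate_constants().
static inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}

// Forward-Euler integration of the coupled compartment chain. Mirrors
// step_network() in R exactly (same update order, same clamping); a test
// asserts equality of the two paths.
// [[Rcpp::export]]
List cpp_simulate_axon(NumericVector V0, NumericVector m0, NumericVector h0,
                       NumericVector n0, double gNa, double gK, double gL,
                       double ENa, double EK, double EL, NumericVector Ctot,
                       double g_axial, double stim_amplitude,
                       double stim_t_on, double stim_t_off, bool stim_all,
                       int stim_node, bool use_generator, bool proportional,
                       double kappa, int dielectric_node, double v_rest,
                       double dt, int n_steps) {
  int n = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> nn(n0.begin(), n0.end());
  NumericMatrix out(n, n_steps + 1);
  for (int i = 0; i < n; ++i) out(i, 0) = V[i];
  int dnode = dielectric_node - 1;
  int snode = stim_node - 1;
  double gmin = 1.0, gmax = 0.0;
  std::vector<double> Vnew(n);

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    bool on = (t >= stim_t_on) && (t < stim_t_off);
    double Is_now = on ? stim_amplitude : 0.0;
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      double INa = gNa * m[i] * m[i] * m[i] * h[i] * (v - ENa);
      double IK = gK * nn[i] * nn[i] * nn[i] * nn[i] * (v - EK);
      double IL = gL * (v - EL);
      double Iax = 0.0;
      if (i > 0) Iax += g_axial * (V[i - 1] - v);
      if (i < n - 1) Iax += g_axial * (V[i + 1] - v);
      double Ist = 0.0;
      if (on && (stim_all || i == snode)) Ist = stim_amplitude;
      double Idl = 0.0;
      if (use_generator && i == dnode) {
        if (proportional) {
          double dep = v - v_rest;
          Idl = -kappa * (dep > 0.0 ? dep : 0.0);
        } else {
          Idl = -kappa * Is_now;
        }
      }
      Vnew[i] = v + dt * (Ist + Iax + Idl - INa - IK - IL) / Ctot[i];
      if (!std::isfinite(Vnew[i]))
        stop("simulate_axon: numerical instability (non-finite V) at step %d, node %d",
             k + 1, i + 1);
    }
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      double am = alpha_m(v), bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
      double bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
      double an = alpha_n(v), bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
      double mi = m[i] + dt * (am * (1.0 - m[i]) - bm * m[i]);
      double hi = h[i] + dt * (ah * (1.0 - h[i]) - bh * h[i]);
      double ni = nn[i] + dt * (an * (1.0 - nn[i]) - bn * nn[i]);
      m[i] = mi < 0.0 ? 0.0 : (mi > 1.0 ? 1.0 : mi);
      h[i] = hi < 0.0 ? 0.0 : (hi > 1.0 ? 1.0 : hi);
      nn[i] = ni < 0.0 ? 0.0 : (ni > 1.0 ? 1.0 : ni);
      if (m[i] < gmin) gmin = m[i];
      if (h[i] < gmin) gmin = h[i];
      if (nn[i] < gmin) gmin = nn[i];
      if (m[i] > gmax) gmax = m[i];
      if (h[i] > gmax) gmax = h[i];
      if (nn[i] > gmax) gmax = nn[i];
      V[i] = Vnew[i];
      out(i, k + 1) = V[i];
    }
  }
  return List::create(_["V"] = out, _["m"] = NumericVector(m.begin(), m.end()),
                      _["h"] = NumericVector(h.begin(), h.end()),
                      _["n"] = NumericVector(nn.begin(), nn.end()),
                      _["gating_range"] = NumericVector::create(gmin, gmax));
}
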