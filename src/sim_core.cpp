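#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step Euler integration of linear neural dynamics
//   dz/dt = sigma * A z + u(t)
// driving, per node, the balloon-Windkessel haemodynamic model
//   ds/dt = z - kappa s - gamma (f - 1)
//   df/dt = s
//   dv/dt = (f - v^{1/alpha}) / tau
//   dq/dt = (f E(f)/E0 - v^{1/alpha} q / v) / tau,  E(f) = 1 - (1-E0)^{1/f}
// with BOLD output y = V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)),
// k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.
//
// `u` is an n x steps matrix of external inputs (already includes burn-in
// steps); BOLD is sampled at the end of every `sample_every` steps after the
// first `burn_steps` steps. tau may differ per node (haemodynamic lag
// variability).
// [[Rcpp::export]]
NumericMatrix sim_bold_core(const NumericMatrix& A, double sigma,
                            const NumericMatrix& u, const NumericVector& tau,
                            double kappa, double gamma_r, double alpha,
                            double E0, double V0, double dt,
                            int sample_every, int burn_steps) {
  const int n = A.nrow();
  const int steps = u.ncol();
  if (A.ncol() != n) stop("A must be square");
  if (u.nrow() != n) stop("u must have one row per node");
  if (tau.size() != n) stop("tau must have one entry per node");
  const int n_samp = (steps - burn_steps) / sample_every;
  if (n_samp < 1) stop("too few integration steps for one sample");

  std::vector<double> z(n, 0.0), s(n, 0.0), f(n, 1.0), v(n, 1.0), q(n, 1.0);
  std::vector<double> dz(n, 0.0);
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double ia = 1.0 / alpha;
  const double log1mE0 = std::log(1.0 - E0);
  NumericMatrix out(n, n_samp);
  int isamp = 0;

  // sparse representation of the off-diagonal coupling (A is sparse by design)
  std::vector<int> e_from, e_to;
  std::vector<double> e_w, a_diag(n);
  for (int i = 0; i < n; ++i) a_diag[i] = A(i, i);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && A(i, j) != 0.0) {
        e_to.push_back(i);
        e_from.push_back(j);
        e_w.push_back(A(i, j));
      }
  const int n_edges = (int)e_w.size();

  for (int t = 0; t < steps; ++t) {
    // neural drift: sigma * A z + u_t
    for (int i = 0; i < n; ++i) dz[i] = a_diag[i] * z[i];
    for (int e = 0; e < n_edges; ++e) dz[e_to[e]] += e_w[e] * z[e_from[e]];
    for (int i = 0; i < n; ++i) z[i] += dt * (sigma * dz[i] + u(i, t));

    for (int i = 0; i < n; ++i) {
      const double fi = f[i];
      const double Ef = 1.0 - std::exp(log1mE0 / fi);
      const double via = std::exp(ia * std::log(v[i]));
      const double ds = z[i] - kappa * s[i] - gamma_r * (fi - 1.0);
      const double dvi = (fi - via) / tau[i];
      const double dqi = (fi * Ef / E0 - via * q[i] / v[i]) / tau[i];
      s[i] += dt * ds;
      f[i] += dt * s[i];
      v[i] += dt * dvi;
      q[i] += dt * dqi;
      if (f[i] < 1e-6) f[i] = 1e-6;
      if (v[i] < 1e-6) v[i] = 1e-6;
      if (q[i] < 1e-9) q[i] = 1e-9;
      if (!std::isfinite(z[i]) || !std::isfinite(v[i]) || !std::isfinite(q[i]))
        stop("simulation diverged (non-finite state) at step %d", t + 1);
    }

    if (t >= burn_steps && ((t - burn_steps + 1) % sample_every) == 0 &&
        isamp < n_samp) {
      for (int i = 0; i < n; ++i) {
        const double y =
            V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                  k3 * (1.0 - v[i]));
        if (!std::isfinite(y))
          stop("simulation diverged (non-finite BOLD) at step %d", t + 1);
        out(i, isamp) = y;
      }
      ++isamp;
    }
  }
  return out;
}

// Peak latency (seconds, relative to stimulus onset) of the BOLD response of
// a single node to a brief unit-area neural input pulse. Used to calibrate
// the transit-time jitter that realizes a requested haemodynamic-lag SD.
// [[Rcpp::export]]
double hrf_peak_latency(double tau, double sigma, double kappa, double gamma_r,
                        double alpha, double E0, double V0, double dt,
                        double t_max) {
  const int steps = (int)(t_max / dt);
  double z = 0.0, s = 0.0, f = 1.0, v = 1.0, q = 1.0;
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double ia = 1.0 / alpha;
  double best = R_NegInf;
  int best_t = 0;
  for (int t = 0; t < steps; ++t) {
    const double u = (t == 0) ? 1.0 / dt : 0.0; // unit-area impulse
    z += dt * (-sigma * z + u);
    const double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f);
    const double via = std::pow(v, ia);
    const double ds = z - kappa * s - gamma_r * (f - 1.0);
    const double dv = (f - via) / tau;
    const double dq = (f * Ef / E0 - via * q / v) / tau;
    s += dt * ds;
    f += dt * s;
    v += dt * dv;
    q += dt * dq;
    if (f < 1e-6) f = 1e-6;
    if (v < 1e-6) v = 1e-6;
    const double y = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    if (y > best) {
      best = y;
      best_t = t;
    }
  }
  return (best_t + 1) * dt;
}
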