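#include <Rcpp.h>
using namespace Rcpp;

// Unordered pairs (i < j) of points within `radius` (Euclidean), brute force.
// Returns 1-based indices and the pair distances.
// [[Rcpp::export(name = "radius_pairs_cpp")]]
List radius_pairs_cpp(NumericVector x, NumericVector y, NumericVector z,
                      double radius) {
  const int n = x.size();
  const double r2 = radius * radius;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double dz = z[i] - z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["dist"] = wrap(dd));
}

// Classical fixed-step RK4 for the Kuramoto system
//   dtheta_i/dt = omega + K * sum_j A_ij sin(theta_j - theta_i)
// with A a symmetric 0/1 adjacency in compressed sparse column form
// (p: column pointers, idx: 0-based row indices). Phases are integrated
// unwrapped. Returns a (n_checkpoints + 1) x N matrix of checkpoint states,
// the first row being theta0.
struct DerivWorkspace {
  std::vector<double> s, c, As, Ac;
  explicit DerivWorkspace(int n) : s(n), c(n), As(n), Ac(n) {}
};

static void kuramoto_deriv(const int* p, const int* idx, int n,
                           double K, double omega,
                           const std::vector<double>& theta,
                           std::vector<double>& dtheta, DerivWorkspace& w) {
  for (int i = 0; i < n; ++i) {
    w.s[i] = std::sin(theta[i]);
    w.c[i] = std::cos(theta[i]);
    w.As[i] = 0.0;
    w.Ac[i] = 0.0;
  }
  for (int j = 0; j < n; ++j) {
    const double sj = w.s[j], cj = w.c[j];
    for (int k = p[j]; k < p[j + 1]; ++k) {
      const int i = idx[k];
      w.As[i] += sj;
      w.Ac[i] += cj;
    }
  }
  for (int i = 0; i < n; ++i)
    dtheta[i] = omega + K * (w.c[i] * w.As[i] - w.s[i] * w.Ac[i]);
}

// [[Rcpp::export(name = "kuramoto_rk4_cpp")]]
NumericMatrix kuramoto_rk4_cpp(NumericVector theta0, IntegerVector p,
                               IntegerVector idx, double K, double omega,
                               double dt, int steps_per_checkpoint,
                               int n_checkpoints) {
  const int n = theta0.size();
  if (p.size() != n + 1)
    stop("adjacency dimension does not match theta0");
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  DerivWorkspace w(n);
  const int* pp = p.begin();
  const int* pidx = idx.begin();
  NumericMatrix out(n_checkpoints + 1, n);
  for (int i = 0; i < n; ++i) out(0, i) = th[i];

  for (int cp = 1; cp <= n_checkpoints; ++cp) {
    for (int s = 0; s < steps_per_checkpoint; ++s) {
      kuramoto_deriv(pp, pidx, n, K, omega, th, k1, w);
      for (int i = 0; i < n; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
      kuramoto_deriv(pp, pidx, n, K, omega, tmp, k2, w);
      for (int i = 0; i < n; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
      kuramoto_deriv(pp, pidx, n, K, omega, tmp, k3, w);
      for (int i = 0; i < n; ++i) tmp[i] = th[i] + dt * k3[i];
      kuramoto_deriv(pp, pidx, n, K, omega, tmp, k4, w);
      for (int i = 0; i < n; ++i)
        th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(th[i]))
        stop("non-finite phase at checkpoint %d (oscillator %d): "
             "integration diverged", cp, i + 1);
      out(cp, i) = th[i];
    }
  }
  return out;
}
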