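#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared with R/network.R (cpp_param_vector()).
enum {
  P_K1, P_K2, P_CMAX, P_K3GC, P_ALPHA1, P_ALPHA2, P_K4, P_K5,
  P_K6EFF, P_K9EFF, P_OM1, P_OM2, P_K7, P_K7B, P_N1, P_K8,
  P_K10, P_K10B, P_N2, P_K11, P_K12, P_K13, P_K14, P_K15, P_K16,
  P_D, P_EPS, NPAR
};

// State order: c1, c2, AHL1, AHL2, C1, C2, preRes1, Res1, Res2
static inline double hill(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  if (n == 1.0) return x / (K + x);
  double xn = std::pow(x, n);
  return xn / (std::pow(K, n) + xn);
}

static inline void propensities(const double* x, const double* p, double* a) {
  double L = 1.0 - (x[0] + x[1]) / p[P_CMAX];
  if (L < 0.0) L = 0.0;
  a[0]  = p[P_K1] * x[0] * L;
  a[1]  = p[P_K2] * x[1] * L;
  a[2]  = p[P_K3GC] * x[0] / (1.0 + p[P_ALPHA1] * x[7]);
  a[3]  = p[P_K3GC] * x[1] / (1.0 + p[P_ALPHA2] * x[8]);
  a[4]  = p[P_K4] * x[0];
  a[5]  = p[P_K5] * x[1];
  a[6]  = p[P_K6EFF] * x[3] * x[3] / p[P_OM1];
  a[7]  = p[P_OM1] * p[P_K7] * hill(x[5] / p[P_OM1], p[P_K7B], p[P_N1]);
  a[8]  = p[P_K8] * x[6];
  a[9]  = p[P_K9EFF] * x[2] * x[2] / p[P_OM2];
  a[10] = p[P_OM2] * p[P_K10] * hill(x[4] / p[P_OM2], p[P_K10B], p[P_N2]);
  a[11] = p[P_K11] * x[2];
  a[12] = p[P_K12] * x[3];
  a[13] = p[P_K13] * x[4];
  a[14] = p[P_K14] * x[5];
  a[15] = p[P_K15] * x[7];
  a[16] = p[P_K16] * x[8];
  a[17] = p[P_D] * x[1];
}

// Net change per species: S %*% a for the 9x18 stoichiometry.
static inline void drift_from_prop(const double* a, double* f) {
  f[0] = a[0] - a[2];
  f[1] = a[1] - a[3] - a[17];
  f[2] = a[4] - 2.0 * a[9] - a[11];
  f[3] = a[5] - 2.0 * a[6] - a[12];
  f[4] = a[9] - a[13];
  f[5] = a[6] - a[14];
  f[6] = a[7] - a[8];
  f[7] = a[8] - a[15];
  f[8] = a[10] - a[16];
}

//' @noRd
// [[Rcpp::export(name = ".cpp_propensities")]]
NumericVector cpp_propensities(NumericVector state, NumericVector par) {
  NumericVector a(18);
  propensities(REAL(state), REAL(par), REAL(a));
  return a;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_drift")]]
NumericVector cpp_drift(NumericVector state, NumericVector par) {
  double a[18];
  NumericVector f(9);
  propensities(REAL(state), REAL(par), a);
  drift_from_prop(a, REAL(f));
  return f;
}

// Euler-Maruyama integration of the chemical Langevin equations.
// One independent Wiener increment per reaction channel; negative
// excursions clamped at zero; populations absorbed below `thr`.
//' @noRd
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector x0, NumericVector par, double dt,
                  int n_steps, int record_every, double thr,
                  bool stochastic) {
  const double* p = REAL(par);
  double x[9], a[18], f[9];
  for (int i = 0; i < 9; ++i) x[i] = x0[i];

  int n_rec = n_steps / record_every + 1;
  bool extra = (n_steps % record_every) != 0;
  if (extra) n_rec += 1;
  NumericMatrix states(n_rec, 9);
  NumericVector times(n_rec);
  int rec = 0;
  times[rec] = 0.0;
  for (int i = 0; i < 9; ++i) states(rec, i) = x[i];
  ++rec;

  double extinct_at = NA_REAL;
  const double sdt = std::sqrt(dt);
  const double eps = p[P_EPS];
  RNGScope scope;

  for (int s = 1; s <= n_steps; ++s) {
    propensities(x, p, a);
    drift_from_prop(a, f);
    for (int i = 0; i < 9; ++i) x[i] += f[i] * dt;

    if (stochastic && eps > 0.0) {
      double g[18];
      for (int j = 0; j < 18; ++j)
        g[j] = eps * std::sqrt(a[j]) * sdt * norm_rand();
      x[0] += g[0] - g[2];
      x[1] += g[1] - g[3] - g[17];
      x[2] += g[4] - 2.0 * g[9] - g[11];
      x[3] += g[5] - 2.0 * g[6] - g[12];
      x[4] += g[9] - g[13];
      x[5] += g[6] - g[14];
      x[6] += g[7] - g[8];
      x[7] += g[8] - g[15];
      x[8] += g[10] - g[16];
    }

    for (int i = 0; i < 9; ++i) {
      if (!std::isfinite(x[i]))
        stop("non-finite state at t = %f (component %d)", s * dt, i + 1);
      if (x[i] < 0.0) x[i] = 0.0;
    }
    if (x[0] < thr) x[0] = 0.0;
    if (x[1] < thr) x[1] = 0.0;
    if (ISNA(extinct_at) && x[0] == 0.0 && x[1] == 0.0)
      extinct_at = s * dt;

    if (s % record_every == 0 || s == n_steps) {
      times[rec] = s * dt;
      for (int i = 0; i < 9; ++i) states(rec, i) = x[i];
      ++rec;
      if (s == n_steps) break;
    }
  }

  return List::create(_["times"] = times, _["states"] = states,
                      _["extinct_at"] = extinct_at);
}
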