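#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: 0 M_frq, 1 F, 2 M_wc1, 3 W_dark, 4 W_light, 5 V
// Parameter vector layout (fixed order, prepared by the R wrapper):
// 0 v_dark, 1 v_light, 2 K_I, 3 h, 4 d_M, 5 k_s, 6 tau, 7 d_F,
// 8 v_w, 9 k_fw, 10 d_Mw, 11 k_w, 12 d_Wd, 13 d_Wl,
// 14 k_act, 15 k_rel, 16 K_V, 17 k_v, 18 d_V

static inline void rhs(const double *x, double m_del, double light,
                       const double *p, double *dx) {
  double F = x[1] > 0.0 ? x[1] : 0.0;
  double V = x[5] > 0.0 ? x[5] : 0.0;
  double Kh = std::pow(p[2], p[3]);
  double rep = Kh / (Kh + std::pow(F, p[3]));
  double act = p[14] * light * x[3] / (1.0 + V / p[16]);
  dx[0] = (p[0] * x[3] + p[1] * x[4]) * rep - p[4] * x[0];
  dx[1] = p[5] * m_del - p[7] * x[1];
  dx[2] = p[8] + p[9] * x[1] - p[10] * x[2];
  dx[3] = p[11] * x[2] - act + p[15] * x[4] - p[12] * x[3];
  dx[4] = act - p[15] * x[4] - p[13] * x[4];
  dx[5] = p[17] * x[4] - p[18] * x[5];
}

// cubic Lagrange interpolation of the stored M_frq history at fractional
// grid position s (units of dt); known indices are 0..imax
static inline double interp_m(const double *m, double s, int imax,
                              double hist_m) {
  if (s <= 0.0) return hist_m;
  int i0 = (int)std::floor(s);
  int j0 = i0 - 1;
  if (j0 < 0) j0 = 0;
  if (j0 > imax - 3) j0 = imax - 3;
  if (j0 < 0) { // fewer than 4 points known: fall back to linear
    if (i0 >= imax) return m[imax];
    double w = s - i0;
    return (1.0 - w) * m[i0] + w * m[i0 + 1];
  }
  double u = s - j0; // in [0, 3] nominally
  double l0 = -(u - 1.0) * (u - 2.0) * (u - 3.0) / 6.0;
  double l1 = u * (u - 2.0) * (u - 3.0) / 2.0;
  double l2 = -u * (u - 1.0) * (u - 3.0) / 2.0;
  double l3 = u * (u - 1.0) * (u - 2.0) / 6.0;
  return l0 * m[j0] + l1 * m[j0 + 1] + l2 * m[j0 + 2] + l3 * m[j0 + 3];
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix dde_integrate_cpp(NumericVector par, NumericVector light,
                                double dt, NumericVector history) {
  if (par.size() != 19) stop("parameter vector must have length 19");
  if (history.size() != 6) stop("history state must have length 6");
  int n = light.size(); // number of steps
  double tau = par[6];
  double lag = tau / dt; // in steps
  NumericMatrix out(n + 1, 6);
  std::vector<double> mhist(n + 1);
  double x[6], k1[6], k2[6], k3[6], k4[6], xs[6];
  const double *p = REAL(par);
  for (int j = 0; j < 6; ++j) {
    x[j] = history[j];
    out(0, j) = x[j];
  }
  mhist[0] = x[0];
  double hist_m = history[0];
  for (int i = 0; i < n; ++i) {
    double L = light[i]; // light is constant within an aligned step
    double m0 = interp_m(mhist.data(), i - lag, i, hist_m);
    double mh = interp_m(mhist.data(), i + 0.5 - lag, i, hist_m);
    double m1 = interp_m(mhist.data(), i + 1.0 - lag, i, hist_m);
    rhs(x, m0, L, p, k1);
    for (int j = 0; j < 6; ++j) xs[j] = x[j] + 0.5 * dt * k1[j];
    rhs(xs, mh, L, p, k2);
    for (int j = 0; j < 6; ++j) xs[j] = x[j] + 0.5 * dt * k2[j];
    rhs(xs, mh, L, p, k3);
    for (int j = 0; j < 6; ++j) xs[j] = x[j] + dt * k3[j];
    rhs(xs, m1, L, p, k4);
    for (int j = 0; j < 6; ++j) {
      x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(x[j]))
        stop("state became non-finite at t = %.4f h (component %d)",
             (i + 1) * dt, j + 1);
      if (x[j] < 0.0) x[j] = 0.0; // RK4 undershoot clip (order ~dt^5)
      out(i + 1, j) = x[j];
    }
    mhist[i + 1] = x[0];
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericVector periodogram_cpp(NumericVector t, NumericVector x,
                              NumericVector periods) {
  int n = t.size(), np = periods.size();
  if (x.size() != n) stop("time and value vectors differ in length");
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  NumericVector pw(np);
  for (int k = 0; k < np; ++k) {
    double w = 2.0 * M_PI / periods[k];
    double c = 0.0, s = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = x[i] - mean;
      c += xi * std::cos(w * t[i]);
      s += xi * std::sin(w * t[i]);
    }
    pw[k] = (c * c + s * s) * 2.0 / n;
  }
  return pw;
}
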