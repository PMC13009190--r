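#include <Rcpp.h>
#include <cmath>
#include "bessel.h"
using namespace Rcpp;

// mean over the unit sphere of exp(l1 n1^2 + l2 n2^2 + l3 n3^2); see
// watson.cpp for the derivation
static double quadform_mean(double l1, double l2, double l3,
                            const NumericVector& nodes,
                            const NumericVector& wts) {
  double lmax = std::max(l1, std::max(l2, l3));
  l1 -= lmax; l2 -= lmax; l3 -= lmax;
  double acc = 0.0;
  int n = nodes.size();
  for (int q = 0; q < n; ++q) {
    double t2 = nodes[q] * nodes[q];
    double a = l3 * t2 + (1.0 - t2) * 0.5 * (l1 + l2);
    double z = (1.0 - t2) * 0.5 * (l1 - l2);
    acc += wts[q] * std::exp(a + std::fabs(z)) * i0e(z);
  }
  return std::exp(lmax) * 0.5 * acc;
}

static double watson_avg(double cosb, double c, double k, double den,
                         const NumericVector& nodes, const NumericVector& wts) {
  double x = cosb;
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  double s2 = 1.0 - x * x;
  if (!R_finite(k)) return std::exp(-c * x * x);
  double tr = k - c;
  double disc = std::sqrt(tr * tr + 4.0 * k * c * s2);
  double lp = 0.5 * (tr + disc);
  double lm = 0.5 * (tr - disc);
  return quadform_mean(lm, 0.0, lp, nodes, wts) / den;
}

// Residual vector of the NODDI forward model at parameters
// p = (f_iso, f_in, kappa) against the normalised signal y, with fixed
// d_par/d_iso and the orientation entering through cosb = g . mu.
// [[Rcpp::export]]
NumericVector noddi_resid_cpp(NumericVector p, NumericVector y,
                              NumericVector cosb, NumericVector b,
                              double d_par, double d_iso,
                              NumericVector nodes, NumericVector wts) {
  double f_iso = p[0], f_in = p[1], k = p[2];
  double den = R_finite(k) ? quadform_mean(0.0, 0.0, k, nodes, wts) : 1.0;
  double d_perp = d_par * (1.0 - f_in);
  int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s_in = watson_avg(cosb[i], b[i] * d_par, k, den, nodes, wts);
    double s_en = std::exp(-b[i] * d_perp) *
      watson_avg(cosb[i], b[i] * (d_par - d_perp), k, den, nodes, wts);
    double pred = (1.0 - f_iso) * (f_in * s_in + (1.0 - f_in) * s_en) +
      f_iso * std::exp(-b[i] * d_iso);
    out[i] = pred - y[i];
  }
  return out;
}

// [[Rcpp::export]]
double noddi_sse_cpp(NumericVector p, NumericVector y, NumericVector cosb,
                     NumericVector b, double d_par, double d_iso,
                     NumericVector nodes, NumericVector wts) {
  NumericVector r = noddi_resid_cpp(p, y, cosb, b, d_par, d_iso, nodes, wts);
  double sse = 0.0;
  for (int i = 0; i < r.size(); ++i) sse += r[i] * r[i];
  return sse;
}

// Residual vector of the powder-averaged SANDI model at
// p = (f_ec, f_in, r_s, d_in, d_ec) against per-shell means y.
// Sphere signals are linearly interpolated from a precomputed
// (radius grid x shell) table to keep the hot loop series-free.
// [[Rcpp::export]]
NumericVector sandi_resid_cpp(NumericVector p, NumericVector y,
                              NumericVector bshell, NumericVector r_grid,
                              NumericMatrix sph_grid) {
  double f_ec = p[0], f_in = p[1], r_s = p[2], d_in = p[3], d_ec = p[4];
  int n = y.size();
  double r0 = r_grid[0];
  double dr = r_grid[1] - r_grid[0];
  double fi = (r_s - r0) / dr;
  int i0 = (int)std::floor(fi);
  if (i0 < 0) i0 = 0;
  if (i0 > r_grid.size() - 2) i0 = r_grid.size() - 2;
  double w = fi - i0;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double bd = bshell[i] * d_in;
    double s_in = bd < 1e-12 ? 1.0
      : std::sqrt(M_PI) / (2.0 * std::sqrt(bd)) * std::erf(std::sqrt(bd));
    double s_is = sph_grid(i0, i) * (1.0 - w) + sph_grid(i0 + 1, i) * w;
    double s_ec = std::exp(-bshell[i] * d_ec);
    double pred = (1.0 - f_ec) * (f_in * s_in + (1.0 - f_in) * s_is) +
      f_ec * s_ec;
    out[i] = pred - y[i];
  }
  return out;
}

// [[Rcpp::export]]
double sandi_sse_cpp(NumericVector p, NumericVector y, NumericVector bshell,
                     NumericVector r_grid, NumericMatrix sph_grid) {
  NumericVector r = sandi_resid_cpp(p, y, bshell, r_grid, sph_grid);
  double sse = 0.0;
  for (int i = 0; i < r.size(); ++i) sse += r[i] * r[i];
  return sse;
}
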