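#include <Rcpp.h>
#include <cmath>
#include "bessel.h"
using namespace Rcpp;

// Mean over the unit sphere of exp(l1*n1^2 + l2*n2^2 + l3*n3^2), computed by
// reducing the azimuthal integral to a Bessel-I0 kernel and applying
// Gauss-Legendre quadrature in cos(theta):
//   (1/4pi) \int exp(sum li ni^2) dn
//     = (1/2) \int_{-1}^{1} exp(l3 t^2 + (1-t^2)(l1+l2)/2) I0((1-t^2)(l1-l2)/2) dt
// Evaluated in log space relative to max(li) for stability.
static double sphere_exp_quadform(double l1, double l2, double l3,
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

// Watson-averaged stick attenuation:
//   S(g) = E_{n ~ Watson(mu, kappa)}[ exp(-c (g.n)^2) ]
// with c = b * d_parallel and cosbeta = g . mu. The integrand is
// exp(n' Q n) with Q = kappa mu mu' - c g g', a rank-2 quadratic form whose
// nonzero eigenvalues follow from the 2x2 block in span{mu, g}.
// [[Rcpp::export]]
NumericVector watson_stick_cpp(NumericVector cosbeta, NumericVector cvec,
                               NumericVector kappa,
                               NumericVector nodes, NumericVector wts) {
  int n = cosbeta.size();
  NumericVector out(n);
  double last_k = NA_REAL, last_den = NA_REAL;  // normalisations repeat within a voxel
  for (int i = 0; i < n; ++i) {
    double k = kappa[i], c = cvec[i], x = cosbeta[i];
    if (x > 1.0) x = 1.0;
    if (x < -1.0) x = -1.0;
    double s2 = 1.0 - x * x;
    if (!R_finite(k)) {  // coherent stick limit
      out[i] = std::exp(-c * x * x);
      continue;
    }
    double tr = k - c;
    double disc = std::sqrt(tr * tr + 4.0 * k * c * s2);
    double lp = 0.5 * (tr + disc);
    double lm = 0.5 * (tr - disc);
    double num = sphere_exp_quadform(lm, 0.0, lp, nodes, wts);
    if (k != last_k) {
      last_den = sphere_exp_quadform(0.0, 0.0, k, nodes, wts);
      last_k = k;
    }
    out[i] = num / last_den;
  }
  return out;
}
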