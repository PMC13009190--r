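#ifndef HIPPDIFF_BESSEL_H
#define HIPPDIFF_BESSEL_H

#include <cmath>

// Scaled modified Bessel function I0(x) * exp(-|x|), Abramowitz & Stegun
// 9.8.1-9.8.2 polynomial approximations (|error| < 2e-7).
inline double i0e(double x) {
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75;
    t *= t;
    double p = 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
               t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
    return p * std::exp(-ax);
  }
  double t = 3.75 / ax;
  double p = 0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
             t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
             t * (-0.01647633 + t * 0.00392377)))))));
  return p / std::sqrt(ax);
}

#endif
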