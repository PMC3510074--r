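// Euler-Maruyama integration of the overdamped radial escape from a
// potential well: dr = -u'(r)/gamma dt + sqrt(2 D_r) dW, reflecting at
// r = 0, absorbing at r = a. The radial profile is the piecewise
// quadratic-Hermite-quadratic construction of potential_well(); its
// derivative is evaluated inline from the piece parameters.

#include <Rcpp.h>
using namespace Rcpp;

static inline double profile_deriv(double r, double a, double r0, double r1,
                                   double k0, double kb,
                                   double u0, double u1,
                                   double s0, double s1) {
  if (r >= a) return 0.0;
  if (r <= r0) return k0 * r;
  if (r >= r1) return kb * (a - r);
  double h = r1 - r0;
  double t = (r - r0) / h;
  return (6.0 * t * t - 6.0 * t) / h * u0 +
         (3.0 * t * t - 4.0 * t + 1.0) * s0 +
         (-6.0 * t * t + 6.0 * t) / h * u1 +
         (3.0 * t * t - 2.0 * t) * s1;
}

// [[Rcpp::export]]
NumericVector escape_times_cpp(int n_rep, double dt, double D_r, double gamma_,
                               double a, double r0, double r1,
                               double k0, double kb, double depth,
                               double u0, double u1, double s0, double s1,
                               double max_steps) {
  NumericVector out(n_rep);
  const double noise = std::sqrt(2.0 * D_r * dt);
  for (int i = 0; i < n_rep; ++i) {
    double r = 0.0;
    double steps = 0.0;
    for (;;) {
      r += -profile_deriv(r, a, r0, r1, k0, kb, u0, u1, s0, s1) / gamma_ * dt +
           noise * norm_rand();
      if (r < 0.0) r = -r;
      steps += 1.0;
      if (r >= a) break;
      if (steps >= max_steps) {
        Rcpp::stop("escape simulation exceeded max_steps; increase dt or max_steps");
      }
    }
    out[i] = steps * dt;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
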