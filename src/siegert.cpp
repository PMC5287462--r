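// Stationary LIF gain function: numerically stable evaluation of the
// mean-first-passage-time integral, vectorized over populations.
//
// Identity used: e^{x^2}(1+erf(x)) = erfcx(-x); for x > 0 this equals
// 2 e^{x^2} - erfcx(x), whose exponential part integrates to
// sqrt(pi)(erfi(b) - erfi(a)). The far-negative tail (x < -20) is handled
// after the substitution x = -e^u, which flattens the ~1/|x| decay so a
// fixed-node Gauss-Legendre rule resolves it to machine precision.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;

// scaled complementary error function for x >= 0
static double erfcx_pos(double x) {
  if (x < 25.0) return std::exp(x * x) * std::erfc(x);
  const double x2 = x * x;
  return (1.0 / (x * SQRT_PI)) *
         (1.0 - 0.5 / x2 + 0.75 / (x2 * x2) - 1.875 / (x2 * x2 * x2) +
          6.5625 / (x2 * x2 * x2 * x2));
}

// imaginary error function for x >= 0; Taylor below the crossover (all
// terms positive), asymptotic series above (truncation below machine
// epsilon relative to e^{x^2})
static double erfi_pos(double x) {
  if (x == 0.0) return 0.0;
  if (x <= 6.0) {
    const double x2 = x * x;
    double term = x, s = x;
    for (int n = 1; n <= 400; ++n) {
      term *= x2 / n;
      const double contrib = term / (2 * n + 1);
      s += contrib;
      if (contrib < 1e-17 * s && n > x2) break;
    }
    return 2.0 / SQRT_PI * s;
  }
  const double ex = std::exp(x * x);
  if (!std::isfinite(ex)) return R_PosInf;
  const double x2 = 2.0 * x * x;
  double term = 1.0, s = 1.0;
  for (int k = 1; k <= 40; ++k) {
    term *= (2.0 * k - 1.0) / x2;
    if (term > 1.0) break;  // past the asymptotic minimum
    s += term;
    if (term < 1e-17) break;
  }
  return ex / (x * SQRT_PI) * s;
}

// Gauss-Legendre quadrature of f over [lo, hi]
template <typename F>
static double gl_quad(const NumericVector& gx, const NumericVector& gw,
                      double lo, double hi, F f) {
  const double hw = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
  double s = 0.0;
  for (int k = 0; k < gx.size(); ++k) s += gw[k] * f(mid + hw * gx[k]);
  return hw * s;
}

// integral of e^{x^2}(1+erf(x)) over [a, b]; Inf when it overflows
static double siegert_integral(double a, double b, const NumericVector& gx,
                               const NumericVector& gw) {
  if (b > 26.5) return R_PosInf;
  double total = 0.0;
  if (a < -20.0) {
    const double c0 = std::min(b, -20.0);
    total += gl_quad(gx, gw, std::log(-c0), std::log(-a), [](double u) {
      const double eu = std::exp(u);
      return erfcx_pos(eu) * eu;
    });
  }
  const double lo = std::max(a, -20.0), hi = std::min(b, 0.0);
  if (lo < hi)
    total += gl_quad(gx, gw, lo, hi, [](double x) { return erfcx_pos(-x); });
  if (b > 0.0) {
    const double a2 = std::max(a, 0.0);
    total += SQRT_PI * (erfi_pos(b) - erfi_pos(a2));
    if (a2 < b)
      total -= gl_quad(gx, gw, a2, b, [](double x) { return erfcx_pos(x); });
  }
  return total;
}

// [[Rcpp::export(name = ".siegert_rates_cpp")]]
NumericVector siegert_rates_cpp(NumericVector mu_abs, NumericVector sigma,
                                NumericVector tau_m, NumericVector tau_r,
                                NumericVector tau_s, NumericVector V_r,
                                NumericVector theta, double gamma_zeta,
                                NumericVector gx, NumericVector gw) {
  const int n = mu_abs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double tm = tau_m[i] * 1e-3, tr = tau_r[i] * 1e-3;
    if (sigma[i] == 0.0) {
      // noiseless limit
      if (mu_abs[i] <= theta[i]) {
        out[i] = 0.0;
      } else {
        out[i] = 1.0 / (tr + tm * std::log((mu_abs[i] - V_r[i]) /
                                           (mu_abs[i] - theta[i])));
      }
      continue;
    }
    const double shift = gamma_zeta * std::sqrt(tau_s[i] / tau_m[i]);
    const double a = (V_r[i] - mu_abs[i]) / sigma[i] + shift;
    const double b = (theta[i] - mu_abs[i]) / sigma[i] + shift;
    const double I = siegert_integral(a, b, gx, gw);
    if (std::isnan(I))
      stop("siegert rate: quadrature failed (mu = %f, sigma = %f)",
           mu_abs[i], sigma[i]);
    out[i] = 1.0 / (tr + tm * SQRT_PI * I);
  }
  return out;
}
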