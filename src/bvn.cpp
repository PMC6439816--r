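#include <Rcpp.h>
using namespace Rcpp;

// Bivariate standard-normal probabilities by Gauss-Legendre quadrature on the
// tetrachoric series (Genz's algorithm; absolute accuracy ~1e-15, well inside
// the 1e-10 the likelihood needs for rare-diagnosis cell probabilities).

static inline double phid(double z) {
  return 0.5 * erfc(-z * M_SQRT1_2);
}

// P(X > dh, Y > dk) for standard bivariate normal with correlation r
static double bvnu(double dh, double dk, double r) {
  if (!R_FINITE(dh) || !R_FINITE(dk)) {
    if (dh == R_PosInf || dk == R_PosInf) return 0.0;
    if (dh == R_NegInf) return (dk == R_NegInf) ? 1.0 : phid(-dk);
    if (dk == R_NegInf) return phid(-dh);
  }
  if (r >= 1.0)  return phid(-std::max(dh, dk));
  if (r <= -1.0) return std::max(0.0, phid(-dh) - phid(dk));

  static const double XW[3][10][2] = {
    { {-0.9324695142031522, 0.1713244923791705},
      {-0.6612093864662647, 0.3607615730481384},
      {-0.2386191860831970, 0.4679139345726904},
      {0,0},{0,0},{0,0},{0,0},{0,0},{0,0},{0,0} },
    { {-0.9815606342467191, 0.04717533638651177},
      {-0.9041172563704750, 0.1069393259953183},
      {-0.7699026741943050, 0.1600783285433464},
      {-0.5873179542866171, 0.2031674267230659},
      {-0.3678314989981802, 0.2334925365383547},
      {-0.1252334085114692, 0.2491470458134029},
      {0,0},{0,0},{0,0},{0,0} },
    { {-0.9931285991850949, 0.01761400713915212},
      {-0.9639719272779138, 0.04060142980038694},
      {-0.9122344282513259, 0.06267204833410906},
      {-0.8391169718222188, 0.08327674157670475},
      {-0.7463319064601508, 0.1019301198172404},
      {-0.6360536807265150, 0.1181945319615184},
      {-0.5108670019508271, 0.1316886384491766},
      {-0.3737060887154196, 0.1420961093183821},
      {-0.2277858511416451, 0.1491729864726037},
      {-0.07652652113349733, 0.1527533871307259} }
  };
  const double twopi = 2.0 * M_PI;
  int ng, lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { ng = 0; lg = 3; }
  else if (ar < 0.75) { ng = 1; lg = 6; }
  else                { ng = 2; lg = 10; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * XW[ng][i][0] + 1.0) / 2.0);
          bvn += XW[ng][i][1] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
          (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 + c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        double sp = std::sqrt(twopi) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b * (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double t = a * (is * XW[ng][i][0] + 1.0);
          double xs = t * t;
          double rs = std::sqrt(1.0 - xs);
          asr = -(bs / xs + hk) / 2.0;
          if (asr > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * XW[ng][i][1] * std::exp(asr) * (ep - sp);
          }
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::min(1.0, std::max(0.0, bvn));
}

//' Lower-tail bivariate normal CDF, vectorised
//'
//' @param h,k upper integration limits (recycled to common length)
//' @param rho correlation(s)
//' @return P(X <= h, Y <= k) elementwise
//' @noRd
// [[Rcpp::export(name = ".pbvn_cpp")]]
NumericVector pbvn_cpp(NumericVector h, NumericVector k, NumericVector rho) {
  R_xlen_t n = std::max(h.size(), std::max(k.size(), rho.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double hi = h[i % h.size()], ki = k[i % k.size()], ri = rho[i % rho.size()];
    if (ISNAN(hi) || ISNAN(ki) || ISNAN(ri)) { out[i] = NA_REAL; continue; }
    out[i] = bvnu(-hi, -ki, ri);
  }
  return out;
}

// Vectorised log of the rectangle probability used by the joint likelihood:
// sign s = +1 codes "below threshold" (unaffected), s = -1 "above" (affected);
// the rectangle P(s1*Z1 <= s1*u1, s2*Z2 <= s2*u2) collapses to one lower-tail
// call with limits s*u and correlation s1*s2*rho.
// [[Rcpp::export(name = ".log_rect2_cpp")]]
NumericVector log_rect2_cpp(NumericVector u1, NumericVector u2,
                            NumericVector s1, NumericVector s2,
                            NumericVector rho) {
  R_xlen_t n = u1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double ri = rho[i % rho.size()];
    double p = bvnu(-s1[i] * u1[i], -s2[i] * u2[i], s1[i] * s2[i] * ri);
    out[i] = std::log(std::max(p, 1e-320));
  }
  return out;
}
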