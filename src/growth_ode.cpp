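// Monod microbial-growth bioreactor dynamics:
//   d(BG)/dt =  muMax * SC/(KS + SC) * BG - KD * BG
//   d(SC)/dt = -(1/YieldC) * muMax * SC/(KS + SC) * BG
// integrated with an adaptive Dormand-Prince 5(4) pair. The active-learning
// loop evaluates this forward map ~10^6 times per experiment, so it lives in
// compiled code; accuracy is cross-checked against a tight-tolerance lsoda
// reference in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

static inline void monod_rhs(const double* y, double* dy,
                             double muMax, double KS, double KD, double Yc) {
  // solver overshoot can leave SC a hair below zero; clip inside the Monod
  // term only (numerical noise, not model behaviour)
  double S = y[1] > 0.0 ? y[1] : 0.0;
  double g = muMax * S / (KS + S) * y[0];
  dy[0] = g - KD * y[0];
  dy[1] = -g / Yc;
}

// [[Rcpp::export(name = ".growth_traj_cpp")]]
NumericMatrix growth_traj_cpp(NumericVector theta, NumericVector times,
                              NumericVector init,
                              double rtol = 1e-8, double atol = 1e-10) {
  if (theta.size() != 4) stop("theta must be (muMax, KS, KD, YieldC)");
  if (init.size() != 2) stop("init must be (BG0, SC0)");
  const double muMax = theta[0], KS = theta[1], KD = theta[2], Yc = theta[3];
  const int nt = times.size();
  NumericMatrix out(nt, 2);

  // Dormand-Prince 5(4) tableau
  static const double c2 = 1. / 5, c3 = 3. / 10, c4 = 4. / 5, c5 = 8. / 9;
  static const double a21 = 1. / 5;
  static const double a31 = 3. / 40, a32 = 9. / 40;
  static const double a41 = 44. / 45, a42 = -56. / 15, a43 = 32. / 9;
  static const double a51 = 19372. / 6561, a52 = -25360. / 2187,
                      a53 = 64448. / 6561, a54 = -212. / 729;
  static const double a61 = 9017. / 3168, a62 = -355. / 33,
                      a63 = 46732. / 5247, a64 = 49. / 176,
                      a65 = -5103. / 18656;
  static const double b1 = 35. / 384, b3 = 500. / 1113, b4 = 125. / 192,
                      b5 = -2187. / 6784, b6 = 11. / 84;
  static const double e1 = 71. / 57600, e3 = -71. / 16695, e4 = 71. / 1920,
                      e5 = -17253. / 339200, e6 = 22. / 525, e7 = -1. / 40;
  (void)c2; (void)c3; (void)c4; (void)c5;

  double y[2] = { init[0], init[1] };
  double t = 0.0, h = 0.05;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2];
  double yt[2], y5[2], err[2];
  monod_rhs(y, k1, muMax, KS, KD, Yc);

  double tprev = 0.0;
  for (int it = 0; it < nt; ++it) {
    double tend = times[it];
    if (tend < tprev) stop("times must be sorted ascending");
    tprev = tend;
    long steps = 0;
    while (t < tend) {
      if (++steps > 2000000L) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
      if (t + h > tend) h = tend - t;
      for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * a21 * k1[i];
      monod_rhs(yt, k2, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      monod_rhs(yt, k3, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      monod_rhs(yt, k4, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      monod_rhs(yt, k5, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
      monod_rhs(yt, k6, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
      monod_rhs(y5, k7, muMax, KS, KD, Yc);
      for (int i = 0; i < 2; ++i) err[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);

      double enorm = 0.0;
      for (int i = 0; i < 2; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double r = err[i] / sc;
        enorm += r * r;
      }
      enorm = std::sqrt(enorm / 2.0);
      if (!std::isfinite(enorm)) { std::fill(out.begin(), out.end(), NA_REAL); return out; }

      if (enorm <= 1.0) { // accept (FSAL: k7 is k1 of the next step)
        t += h;
        y[0] = y5[0]; y[1] = y5[1];
        k1[0] = k7[0]; k1[1] = k7[1];
        double fac = enorm > 0 ? 0.9 * std::pow(enorm, -0.2) : 5.0;
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        h *= std::max(0.1, 0.9 * std::pow(enorm, -0.2));
      }
      if (!(h > 1e-12)) { // step-size collapse: signal integration failure
        std::fill(out.begin(), out.end(), NA_REAL);
        return out;
      }
    }
    out(it, 0) = y[0];
    out(it, 1) = y[1];
  }
  return out;
}
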