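// Adaptive Dormand-Prince 5(4) integration of the three model variants.
// Kept in C++ because cycle detection and the property suites integrate for
// thousands of time units at tight tolerances.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// params in fixed order: A, d, beta, m, gamma, alpha, p, k
struct Pars {
  double A, d, beta, m, gamma, alpha, p, k;
  double pA, N0, R0;
};

static Pars make_pars(const NumericVector& pv) {
  Pars P;
  P.A = pv[0]; P.d = pv[1]; P.beta = pv[2]; P.m = pv[3];
  P.gamma = pv[4]; P.alpha = pv[5]; P.p = pv[6]; P.k = pv[7];
  P.pA = P.p * P.A; P.N0 = P.A / P.d; P.R0 = P.k / P.pA;
  return P;
}

// variant 0: full (S, I, R); 1: reduced (I, R); 2: rescaled (I, R)
static void rhs(int variant, const Pars& P, const double* y, double* dy) {
  if (variant == 0) {
    double S = y[0], I = y[1], R = y[2];
    double h = (I > 0.0) ? P.k : 0.0;
    double inc = P.beta * I * S / (1.0 + P.alpha * I * I);
    dy[0] = (1.0 - P.p) * P.A - inc - P.d * S + P.gamma * R;
    dy[1] = P.pA + inc - (P.d + P.m) * I - h;
    dy[2] = P.m * I - (P.d + P.gamma) * R + h;
  } else if (variant == 1) {
    double I = y[0], R = y[1];
    double q = 1.0 + P.alpha * I * I;
    dy[0] = P.pA - P.k + P.beta * I * (P.N0 - I - R) / q - (P.d + P.m) * I;
    dy[1] = P.m * I - (P.d + P.gamma) * R + P.k;
  } else {
    double I = y[0], R = y[1];
    double q = 1.0 + P.alpha * I * I;
    dy[0] = P.beta * I * (P.N0 - I - R) - (P.d + P.m) * I * q +
            (1.0 - P.R0) * P.pA * q;
    dy[1] = (P.m * I - (P.d + P.gamma) * R + P.pA * P.R0) * q;
  }
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// [[Rcpp::export(name = ".dp45_path")]]
NumericMatrix dp45_path(int variant, NumericVector y0, NumericVector pv,
                        NumericVector times, double rtol, double atol,
                        bool backward) {
  const int dim = (variant == 0) ? 3 : 2;
  if (y0.size() != dim) stop("state dimension mismatch for this variant");
  const int nt = times.size();
  for (int i = 1; i < nt; ++i)
    if (!(times[i] > times[i - 1])) stop("times must be strictly increasing");
  Pars P = make_pars(pv);
  const double sgn = backward ? -1.0 : 1.0;

  NumericMatrix out(nt, dim);
  double y[3], k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], y5[3];
  for (int j = 0; j < dim; ++j) { y[j] = y0[j]; out(0, j) = y0[j]; }

  double t = times[0];
  double hstep = 1e-4;
  rhs(variant, P, y, k1);
  for (int j = 0; j < dim; ++j) k1[j] *= sgn;

  const double hmin = 1e-14;
  const long max_steps = 5000000L;
  long steps = 0;
  long tiny_streak = 0;
  const double span = times[nt - 1] - times[0];
  int iout = 1;

  while (iout < nt) {
    double tend = times[iout];
    bool clipped = false;
    if (t + hstep >= tend) { hstep = tend - t; clipped = true; }
    if (hstep < hmin)
      stop("dp45: step size collapsed at t = %g", t);
    // persistent micro-steps indicate a field discontinuity (e.g. Filippov
    // sliding at the I = 0 treatment switch of the full system)
    if (!clipped && hstep < 1e-9 * span) {
      if (++tiny_streak > 10000)
        stop("dp45: step size collapsed (discontinuity?) at t = %g", t);
    } else tiny_streak = 0;
    if (++steps > max_steps)
      stop("dp45: step size collapsed (step budget) at t = %g", t);

    // stages (k1 holds the FSAL derivative from the previous step)
    for (int j = 0; j < dim; ++j) yt[j] = y[j] + hstep * a21 * k1[j];
    rhs(variant, P, yt, k2);
    for (int j = 0; j < dim; ++j) k2[j] *= sgn;
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + hstep * (a31 * k1[j] + a32 * k2[j]);
    rhs(variant, P, yt, k3);
    for (int j = 0; j < dim; ++j) k3[j] *= sgn;
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + hstep * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    rhs(variant, P, yt, k4);
    for (int j = 0; j < dim; ++j) k4[j] *= sgn;
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + hstep * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
    rhs(variant, P, yt, k5);
    for (int j = 0; j < dim; ++j) k5[j] *= sgn;
    for (int j = 0; j < dim; ++j)
      yt[j] = y[j] + hstep * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
    rhs(variant, P, yt, k6);
    for (int j = 0; j < dim; ++j) k6[j] *= sgn;
    for (int j = 0; j < dim; ++j)
      y5[j] = y[j] + hstep * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
    rhs(variant, P, y5, k7);
    for (int j = 0; j < dim; ++j) k7[j] *= sgn;

    // embedded error estimate
    double err = 0.0;
    for (int j = 0; j < dim; ++j) {
      double y4 = y[j] + hstep * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                  e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
      double d = (y5[j] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / dim);
    if (!std::isfinite(err))
      stop("dp45: non-finite state at t = %g", t);

    if (err <= 1.0) { // accept
      t += hstep;
      for (int j = 0; j < dim; ++j) { y[j] = y5[j]; k1[j] = k7[j]; }
      if (clipped) {
        for (int j = 0; j < dim; ++j) out(iout, j) = y[j];
        t = tend; // kill accumulated round-off
        ++iout;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    hstep = std::min(hstep * fac, times[nt - 1] - times[0]);
    if (hstep <= 0) hstep = hmin * 2;
  }
  return out;
}
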