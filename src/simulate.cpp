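#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Kinetic core for an N-species batch consortium.
//
// State layout (3 + 2N): S, A, L, X_1, Xm_1, ..., X_N, Xm_N  [g/L]
// Parameter matrix P: 17 rows (slot order below) x N columns.
// Capability matrix caps: 4 rows x N columns
//   (produces_acetate, produces_lactate, consumes_acetate, consumes_lactate).
// Interaction matrix ef: N x N, ef(i, j) = effect of species j on species i;
//   diagonal ignored.  Growth multiplier: clamp(1 - X_j / ef_ij, 0, phi_cap).
//
// Slot order (must match R's param_slots()):
//  0 mu_max   1 K_s     2 Y_sx    3 Y_a     4 Y_l     5 I_a     6 I_l
//  7 k_d      8 t_lag   9 mu_maxA 10 K_sA   11 Y_sxA  12 mu_maxL
// 13 K_sL    14 Y_sxL  15 K_rep  16 m_s

static const double PHI_CAP = 2.0;

static inline double clamp01cap(double x) {
  if (x < 0.0) return 0.0;
  if (x > PHI_CAP) return PHI_CAP;
  return x;
}

static void consortium_rhs(double t,
                           const std::vector<double>& y,
                           std::vector<double>& dy,
                           const NumericMatrix& P,
                           const IntegerMatrix& caps,
                           const NumericMatrix& ef,
                           bool has_ef,
                           int N) {
  const double S = std::max(y[0], 0.0);
  const double A = std::max(y[1], 0.0);
  const double L = std::max(y[2], 0.0);

  double dS = 0.0, dA = 0.0, dL = 0.0;

  for (int i = 0; i < N; ++i) {
    const double X = std::max(y[3 + 2 * i], 0.0);
    double mu = 0.0, muA = 0.0, muL = 0.0;
    const double t_lag = P(8, i);

    if (t >= t_lag) {
      // primary growth: Monod x non-competitive acid inhibition x interactions
      mu = P(0, i) * S / (P(1, i) + S)
         * P(5, i) / (P(5, i) + A)
         * P(6, i) / (P(6, i) + L);
      if (has_ef) {
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          const double Xj = std::max(y[3 + 2 * j], 0.0);
          mu *= clamp01cap(1.0 - Xj / ef(i, j));
        }
      }
      // secondary growth on acids, repressed while primary substrate remains
      const double rep = P(15, i) / (P(15, i) + S);
      if (caps(2, i) && P(9, i) > 0.0)
        muA = P(9, i) * A / (P(10, i) + A) * rep;
      if (caps(3, i) && P(12, i) > 0.0)
        muL = P(12, i) * L / (P(13, i) + L) * rep;
    }

    const double mu_tot = mu + muA + muL;
    dy[3 + 2 * i] = (mu_tot - P(7, i)) * X;  // live biomass
    dy[4 + 2 * i] = mu_tot * X;              // measured (cumulative) biomass

    dS -= (mu / P(2, i) + P(16, i)) * X;
    if (caps(0, i)) dA += P(3, i) * (mu / P(2, i)) * X;
    if (caps(1, i)) dL += P(4, i) * (mu / P(2, i)) * X;
    if (caps(2, i) && P(11, i) > 0.0) dA -= (muA / P(11, i)) * X;
    if (caps(3, i) && P(14, i) > 0.0) dL -= (muL / P(14, i)) * X;
  }

  // no consumption once a pool is (numerically) exhausted
  if (S <= 0.0 && dS < 0.0) dS = 0.0;
  if (A <= 0.0 && dA < 0.0) dA = 0.0;
  if (L <= 0.0 && dL < 0.0) dL = 0.0;

  dy[0] = dS;
  dy[1] = dA;
  dy[2] = dL;
}

// Dormand-Prince 5(4) coefficients
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
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix P, IntegerMatrix caps,
                  Nullable<NumericMatrix> ef_, NumericVector y0,
                  NumericVector t_out, double rtol, double atol,
                  double max_steps) {
  const int N = P.ncol();
  const int d = 3 + 2 * N;
  if ((int) y0.size() != d) stop("state dimension mismatch");

  NumericMatrix ef;
  bool has_ef = ef_.isNotNull() && N > 1;
  if (has_ef) ef = NumericMatrix(ef_);

  const int nt = t_out.size();
  NumericMatrix out(nt, d);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d),
      ytmp(d), yerr(d), ynew(d);

  // breakpoints: output times plus each species' lag time (integration is
  // restarted there so the lag switch never sits inside a step)
  std::vector<double> stops(t_out.begin(), t_out.end());
  for (int i = 0; i < N; ++i) {
    double tl = P(8, i);
    if (tl > t_out[0] && tl < t_out[nt - 1]) stops.push_back(tl);
  }
  std::sort(stops.begin(), stops.end());
  stops.erase(std::unique(stops.begin(), stops.end()), stops.end());

  double t = t_out[0];
  int iout = 0;
  // record initial point if grid starts at t
  if (t_out[0] == t) {
    for (int k = 0; k < d; ++k) out(0, k) = y[k];
    iout = 1;
  }

  double h = 1e-3;
  long steps = 0;
  bool have_k1 = false;

  for (size_t istop = 1; istop < stops.size(); ++istop) {
    double t_end = stops[istop];
    have_k1 = false;  // restart (lag switch / fresh segment)
    while (t < t_end) {
      if (++steps > (long) max_steps) {
        return List::create(_["status"] = 1, _["last_time"] = t,
                            _["states"] = out);
      }
      if (h > t_end - t) h = t_end - t;
      if (h < 1e-12) { t = t_end; break; }

      if (!have_k1) {
        consortium_rhs(t, y, k1, P, caps, ef, has_ef, N);
        have_k1 = true;
      }
      for (int k = 0; k < d; ++k) ytmp[k] = y[k] + h * a21 * k1[k];
      consortium_rhs(t + c2 * h, ytmp, k2, P, caps, ef, has_ef, N);
      for (int k = 0; k < d; ++k)
        ytmp[k] = y[k] + h * (a31 * k1[k] + a32 * k2[k]);
      consortium_rhs(t + c3 * h, ytmp, k3, P, caps, ef, has_ef, N);
      for (int k = 0; k < d; ++k)
        ytmp[k] = y[k] + h * (a41 * k1[k] + a42 * k2[k] + a43 * k3[k]);
      consortium_rhs(t + c4 * h, ytmp, k4, P, caps, ef, has_ef, N);
      for (int k = 0; k < d; ++k)
        ytmp[k] = y[k] + h * (a51 * k1[k] + a52 * k2[k] + a53 * k3[k] +
                              a54 * k4[k]);
      consortium_rhs(t + c5 * h, ytmp, k5, P, caps, ef, has_ef, N);
      for (int k = 0; k < d; ++k)
        ytmp[k] = y[k] + h * (a61 * k1[k] + a62 * k2[k] + a63 * k3[k] +
                              a64 * k4[k] + a65 * k5[k]);
      consortium_rhs(t + h, ytmp, k6, P, caps, ef, has_ef, N);
      for (int k = 0; k < d; ++k)
        ynew[k] = y[k] + h * (b1 * k1[k] + b3 * k3[k] + b4 * k4[k] +
                              b5 * k5[k] + b6 * k6[k]);
      consortium_rhs(t + h, ynew, k7, P, caps, ef, has_ef, N);

      double err = 0.0;
      for (int k = 0; k < d; ++k) {
        yerr[k] = h * (e1 * k1[k] + e3 * k3[k] + e4 * k4[k] + e5 * k5[k] +
                       e6 * k6[k] + e7 * k7[k]);
        double sk = atol + rtol * std::max(std::fabs(y[k]), std::fabs(ynew[k]));
        double r = yerr[k] / sk;
        err += r * r;
      }
      err = std::sqrt(err / d);

      if (!std::isfinite(err)) {
        return List::create(_["status"] = 2, _["last_time"] = t,
                            _["states"] = out);
      }

      if (err <= 1.0) {  // accept
        t += h;
        for (int k = 0; k < d; ++k) {
          y[k] = ynew[k];
          // clip integrator undershoot on nonnegative states
          if (y[k] < 0.0 && y[k] > -1e-9) y[k] = 0.0;
          k1[k] = k7[k];  // FSAL
        }
        while (iout < nt && t_out[iout] <= t + 1e-12) {
          for (int k = 0; k < d; ++k) out(iout, k) = y[k];
          ++iout;
        }
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
      if (h < 1e-10) h = 1e-10;
    }
  }

  return List::create(_["status"] = 0, _["last_time"] = t, _["states"] = out);
}
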