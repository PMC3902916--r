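// Sigmoid transcription-control ODE and its simulated-annealing fit.
//
// dy/dt = k1 / (1 + exp(-(w * R(t) + b))) - k2 * y
//
// R(t) is a piecewise-linear interpolant of the regulator profile, clamped
// to its boundary values outside the sampled interval. The equation is
// integrated with an adaptive Dormand-Prince 5(4) pair; the annealing fit
// maximises the Pearson correlation between measured and simulated target
// profiles (objective F = 1 - c). The fit loop lives here because a screen
// of thousands of regulator-target pairs evaluates the objective millions
// of times.
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() on the R side makes every fit reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct LinInterp {
  const double* t;
  const double* v;
  int n;
  mutable int hint = 1;  // integration time advances monotonically
  double operator()(double x) const {
    if (x <= t[0]) return v[0];
    if (x >= t[n - 1]) return v[n - 1];
    int i = hint;
    if (i < 1 || i >= n || t[i - 1] > x) i = 1;
    while (t[i] < x) ++i;
    hint = i;
    double f = (x - t[i - 1]) / (t[i] - t[i - 1]);
    return v[i - 1] + f * (v[i] - v[i - 1]);
  }
};

inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct OdeParams {
  double k1, k2, w, b;
};

inline double deriv(double tt, double y, const OdeParams& p, const LinInterp& R) {
  return p.k1 * sigmoid(p.w * R(tt) + p.b) - p.k2 * y;
}

// Dormand-Prince 5(4) Butcher tableau.
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights (error = 5th - 4th solution).
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Dense-output coefficients of the Dormand-Prince 5(4) pair (order-4
// continuous extension).
const double d1 = -12715105075.0 / 11282082432.0,
             d3 = 87487479700.0 / 32700410799.0,
             d4 = -10690763975.0 / 1880347072.0,
             d5 = 701980252875.0 / 199316789632.0,
             d6 = -1453857185.0 / 822651844.0,
             d7 = 69997945.0 / 29380423.0;

// Integrate over [times[0], times[nt-1]] with free adaptive steps; grid
// values are read off the continuous extension of each accepted step.
// Returns false on failure (step underflow / step limit / non-finite).
bool integrate_grid(const OdeParams& p, const LinInterp& R, double y0,
                    const double* times, int nt, double rtol, double atol,
                    double* out) {
  R.hint = 1;
  out[0] = y0;
  if (nt == 1) return true;
  double t = times[0], t_end = times[nt - 1];
  double y = y0;
  double h = (t_end - t) * 0.05;
  double k1s = deriv(t, y, p, R);
  int next_out = 1;
  int nsteps = 0;
  const int max_steps = 100000;
  while (t < t_end) {
    if (++nsteps > max_steps) return false;
    if (t + h > t_end) h = t_end - t;
    double k2s = deriv(t + c2 * h, y + h * a21 * k1s, p, R);
    double k3s = deriv(t + c3 * h, y + h * (a31 * k1s + a32 * k2s), p, R);
    double k4s = deriv(t + c4 * h, y + h * (a41 * k1s + a42 * k2s + a43 * k3s), p, R);
    double k5s = deriv(t + c5 * h,
                       y + h * (a51 * k1s + a52 * k2s + a53 * k3s + a54 * k4s), p, R);
    double k6s = deriv(t + h,
                       y + h * (a61 * k1s + a62 * k2s + a63 * k3s + a64 * k4s + a65 * k5s),
                       p, R);
    double ynew = y + h * (b1 * k1s + b3 * k3s + b4 * k4s + b5 * k5s + b6 * k6s);
    double k7s = deriv(t + h, ynew, p, R);
    double err = h * (e1 * k1s + e3 * k3s + e4 * k4s + e5 * k5s + e6 * k6s + e7 * k7s);
    double sk = atol + rtol * std::max(std::fabs(y), std::fabs(ynew));
    double ratio = std::fabs(err) / sk;
    if (!std::isfinite(ratio)) return false;
    if (ratio <= 1.0) {
      // continuous extension: y(t + theta h), theta in [0, 1]
      double ydiff = ynew - y;
      double bspl = h * k1s - ydiff;
      double rc4 = ydiff - h * k7s - bspl;
      double rc5 = h * (d1 * k1s + d3 * k3s + d4 * k4s + d5 * k5s +
                        d6 * k6s + d7 * k7s);
      while (next_out < nt && times[next_out] <= t + h + 1e-14) {
        double theta = (times[next_out] - t) / h;
        if (theta > 1.0) theta = 1.0;
        out[next_out] = y + theta * (ydiff + (1.0 - theta) *
                        (bspl + theta * (rc4 + (1.0 - theta) * rc5)));
        ++next_out;
      }
      t += h;
      y = ynew;
      k1s = k7s;  // FSAL
    }
    double fac = ratio > 0 ? 0.9 * std::pow(ratio, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-12) return false;
  }
  while (next_out < nt) { out[next_out] = y; ++next_out; }
  return true;
}

double pearson(const double* x, const double* y, int n) {
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// F = 1 - Pearson(measured, simulated); constant or failed simulation -> 2.
double objective_of(const OdeParams& p, const LinInterp& R, double y0,
                    const double* times, int nt, const double* measured,
                    double rtol, double atol, std::vector<double>& work) {
  if (!integrate_grid(p, R, y0, times, nt, rtol, atol, work.data()))
    return 2.0;
  double c = pearson(measured, work.data(), nt);
  if (!std::isfinite(c)) return 2.0;
  return 1.0 - c;
}

// Fold x into [lo, hi] by reflection at the boundaries. Proposal steps are
// small relative to the span, so a few reflections always suffice.
inline double reflect_into(double x, double lo, double hi) {
  if (hi <= lo) return lo;
  for (int i = 0; i < 64; ++i) {
    if (x < lo) x = 2.0 * lo - x;
    else if (x > hi) x = 2.0 * hi - x;
    else return x;
  }
  return std::min(std::max(x, lo), hi);
}

}  // namespace

// [[Rcpp::export(name = ".ode_sigmoid_cpp")]]
NumericVector ode_sigmoid_cpp(double k1, double k2, double w, double b,
                              NumericVector reg_times, NumericVector reg_values,
                              double y0, NumericVector times,
                              double rtol, double atol) {
  LinInterp R{reg_times.begin(), reg_values.begin(), (int)reg_times.size()};
  OdeParams p{k1, k2, w, b};
  int nt = times.size();
  NumericVector out(nt);
  if (!integrate_grid(p, R, y0, times.begin(), nt, rtol, atol, out.begin()))
    stop("ODE solver failed (step size underflow or step limit)");
  return out;
}

// Multi-restart simulated annealing for one regulator-target pair.
// init_lo / init_hi: length-4 bounds (k1, k2, w, b) for the uniform initial
// draw; scales: per-parameter Gaussian proposal scales, multiplied by
// sqrt(T) as the chain cools. k1, k2, w are reflected at zero.
// [[Rcpp::export(name = ".anneal_fit_cpp")]]
List anneal_fit_cpp(NumericVector measured, NumericVector reg_times,
                    NumericVector reg_values, NumericVector times,
                    double y0, int n_restarts,
                    NumericVector init_lo, NumericVector init_hi,
                    NumericVector scales, NumericVector prop_lo,
                    NumericVector prop_hi,
                    double t0, double alpha, int n_per_temp, double t_min,
                    double rtol, double atol) {
  LinInterp R{reg_times.begin(), reg_values.begin(), (int)reg_times.size()};
  int nt = times.size();
  std::vector<double> work(nt);
  RNGScope scope;

  NumericMatrix restart_params(n_restarts, 4);
  NumericVector restart_F(n_restarts);
  double best_F = R_PosInf;
  int best_restart = -1;
  OdeParams best_p{0, 0, 0, 0};

  for (int r = 0; r < n_restarts; ++r) {
    double cur[4];
    for (int j = 0; j < 4; ++j)
      cur[j] = init_lo[j] + unif_rand() * (init_hi[j] - init_lo[j]);
    OdeParams pc{cur[0], cur[1], cur[2], cur[3]};
    double Fc = objective_of(pc, R, y0, times.begin(), nt, measured.begin(),
                             rtol, atol, work);
    double chain_best_F = Fc;
    double chain_best[4] = {cur[0], cur[1], cur[2], cur[3]};

    for (double T = t0; T > t_min; T *= alpha) {
      double step_fac = std::sqrt(T);
      for (int it = 0; it < n_per_temp; ++it) {
        double prop[4];
        for (int j = 0; j < 4; ++j)
          prop[j] = reflect_into(cur[j] + norm_rand() * scales[j] * step_fac,
                                 prop_lo[j], prop_hi[j]);
        OdeParams pp{prop[0], prop[1], prop[2], prop[3]};
        double Fp = objective_of(pp, R, y0, times.begin(), nt,
                                 measured.begin(), rtol, atol, work);
        double dF = Fp - Fc;
        if (dF <= 0 || unif_rand() < std::exp(-dF / T)) {
          for (int j = 0; j < 4; ++j) cur[j] = prop[j];
          Fc = Fp;
          if (Fc < chain_best_F) {
            chain_best_F = Fc;
            for (int j = 0; j < 4; ++j) chain_best[j] = cur[j];
          }
        }
      }
    }
    for (int j = 0; j < 4; ++j) restart_params(r, j) = chain_best[j];
    restart_F[r] = chain_best_F;
    if (chain_best_F < best_F) {
      best_F = chain_best_F;
      best_restart = r;
      best_p = OdeParams{chain_best[0], chain_best[1], chain_best[2], chain_best[3]};
    }
  }

  NumericVector sim(nt, NA_REAL);
  double corr = NA_REAL;
  if (best_restart >= 0 &&
      integrate_grid(best_p, R, y0, times.begin(), nt, rtol, atol, sim.begin()))
    corr = pearson(measured.begin(), sim.begin(), nt);

  colnames(restart_params) = CharacterVector::create("k1", "k2", "w", "b");
  return List::create(
      _["params"] = NumericVector::create(_["k1"] = best_p.k1, _["k2"] = best_p.k2,
                                          _["w"] = best_p.w, _["b"] = best_p.b),
      _["F"] = best_F, _["correlation"] = corr, _["simulated"] = sim,
      _["restart_index"] = best_restart + 1,
      _["restart_F"] = restart_F, _["restart_params"] = restart_params);
}
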