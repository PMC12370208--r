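// Method-of-steps integrator for the two-compartment secretion models.
//
// The delayed term I(t - tau) is read from an ordered buffer of accepted
// solver steps, each stored as a cubic Hermite interpolant (value and
// derivative at both step ends).  Steps never exceed the delay tau, so a
// delayed argument always falls in the already-accepted part of the buffer
// (or in the constant pre-history).  The embedded pair is Bogacki-Shampine
// 2(3) with FSAL (the pair behind MATLAB's ode23/dde23); the accepted
// solution is the third-order one.  X segments are stored alongside I so
// the 1-minute reporting grid can be evaluated densely after integration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  double alpha, beta, gamma, delta, tau, epsilon, kappa;
  bool decay_production;
};

inline double hermite(double th, double h, double y0, double y1,
                      double d0, double d1) {
  double h00 = (1.0 + 2.0 * th) * (1.0 - th) * (1.0 - th);
  double h10 = th * (1.0 - th) * (1.0 - th);
  double h01 = th * th * (3.0 - 2.0 * th);
  double h11 = th * th * (th - 1.0);
  return h00 * y0 + h * h10 * d0 + h01 * y1 + h * h11 * d1;
}

// Dense history of accepted steps (shared across protocol phases).
struct History {
  std::vector<double> ts, te;
  std::vector<double> I0, I1, dI0, dI1;
  std::vector<double> X0, X1, dX0, dX1;
  double pre_I;   // constant value for t before the first segment
  double t_min;   // history is the constant pre_I for t <= t_min

  size_t find_seg(double t) const {
    size_t lo = 0, hi = te.size() - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (te[mid] < t) lo = mid + 1; else hi = mid;
    }
    return lo;
  }

  double eval_I(double t) const {
    if (ts.empty() || t <= t_min) return pre_I;
    if (t >= te.back()) return I1.back();
    size_t k = find_seg(t);
    double h = te[k] - ts[k];
    if (h <= 0.0) return I1[k];
    return hermite((t - ts[k]) / h, h, I0[k], I1[k], dI0[k], dI1[k]);
  }
};

const double TAU_ODE_THRESHOLD = 1e-6;  // delays below this run as plain ODEs

inline void rhs(double t, double I, double X, double delayed_I,
                const Params& p, int phase, double chase_origin,
                double& dI, double& dX) {
  double prod;
  if (phase == 0) {
    prod = p.alpha;
  } else {  // chase: production off, or decaying with the labeled pool
    prod = p.decay_production
               ? p.alpha * std::exp(-p.kappa * (t - chase_origin))
               : 0.0;
  }
  dI = prod - p.beta * delayed_I - p.gamma * delayed_I + p.epsilon * X;
  dX = p.beta * delayed_I - p.delta * X - p.epsilon * X;
}

}  // namespace

// [[Rcpp::export(name = ".dde_integrate_cpp")]]
List dde_integrate_cpp(double t0, double t1, NumericVector y0,
                       List par, bool decay_production,
                       int phase, double chase_origin,
                       List history, double pre_I,
                       double disc_origin,
                       double abs_tol, double rel_tol,
                       double initial_step, double max_step,
                       NumericVector report_times) {
  Params p;
  p.alpha = as<double>(par["alpha"]);
  p.beta = as<double>(par["beta"]);
  p.gamma = as<double>(par["gamma"]);
  p.delta = as<double>(par["delta"]);
  p.tau = as<double>(par["tau"]);
  p.epsilon = as<double>(par["epsilon"]);
  p.kappa = as<double>(par["kappa"]);
  p.decay_production = decay_production;

  const bool use_delay = (p.tau > TAU_ODE_THRESHOLD);

  History H;
  if (history.size() > 0) {
    H.ts = as<std::vector<double> >(history["ts"]);
    H.te = as<std::vector<double> >(history["te"]);
    H.I0 = as<std::vector<double> >(history["I0"]);
    H.I1 = as<std::vector<double> >(history["I1"]);
    H.dI0 = as<std::vector<double> >(history["dI0"]);
    H.dI1 = as<std::vector<double> >(history["dI1"]);
    H.X0 = as<std::vector<double> >(history["X0"]);
    H.X1 = as<std::vector<double> >(history["X1"]);
    H.dX0 = as<std::vector<double> >(history["dX0"]);
    H.dX1 = as<std::vector<double> >(history["dX1"]);
    H.pre_I = as<double>(history["pre_I"]);
    H.t_min = as<double>(history["t_min"]);
  } else {
    H.pre_I = pre_I;
    H.t_min = t0;
  }
  size_t first_new_seg = H.ts.size();

  double t = t0;
  double I = y0[0], X = y0[1];
  double span = t1 - t0;
  double h = initial_step > 0 ? initial_step : 1e-2;
  double hmax = max_step > 0 ? max_step : span;
  if (use_delay && p.tau < hmax) hmax = p.tau;
  if (hmax > span) hmax = span;
  if (h > hmax) h = hmax;

  // delay-induced break points: a step always ends exactly there
  std::vector<double> breaks;
  if (use_delay) {
    double b = disc_origin;
    while (b <= t0 + 1e-12) b += p.tau;
    for (; b < t1 - 1e-12; b += p.tau) breaks.push_back(b);
  }
  breaks.push_back(t1);
  size_t next_break = 0;

  auto delayed = [&](double tq, double Iq) -> double {
    if (!use_delay) return Iq;
    return H.eval_I(tq - p.tau);
  };

  int status = 0;  // 0 ok, 1 step underflow / step cap, 2 non-finite
  double fail_t = NA_REAL;
  long nsteps = 0;
  const long max_steps = 5000000;

  double k1I, k1X;
  rhs(t, I, X, delayed(t, I), p, phase, chase_origin, k1I, k1X);

  while (t < t1 - 1e-12 * std::max(1.0, std::fabs(t1))) {
    if (++nsteps > max_steps) { status = 1; fail_t = t; break; }
    double h_try = h;
    while (next_break < breaks.size() && breaks[next_break] <= t + 1e-12)
      ++next_break;
    if (next_break < breaks.size() && t + h_try > breaks[next_break])
      h_try = breaks[next_break] - t;
    if (h_try < 1e-13 * std::max(1.0, std::fabs(t))) {
      status = 1; fail_t = t; break;
    }

    double t2 = t + 0.5 * h_try;
    double I2 = I + 0.5 * h_try * k1I, X2 = X + 0.5 * h_try * k1X;
    double k2I, k2X;
    rhs(t2, I2, X2, delayed(t2, I2), p, phase, chase_origin, k2I, k2X);

    double t3 = t + 0.75 * h_try;
    double I3 = I + 0.75 * h_try * k2I, X3 = X + 0.75 * h_try * k2X;
    double k3I, k3X;
    rhs(t3, I3, X3, delayed(t3, I3), p, phase, chase_origin, k3I, k3X);

    double tn = t + h_try;
    double In = I + h_try * (2.0 / 9.0 * k1I + 1.0 / 3.0 * k2I + 4.0 / 9.0 * k3I);
    double Xn = X + h_try * (2.0 / 9.0 * k1X + 1.0 / 3.0 * k2X + 4.0 / 9.0 * k3X);
    double k4I, k4X;
    rhs(tn, In, Xn, delayed(tn, In), p, phase, chase_origin, k4I, k4X);

    double errI = h_try * (-5.0 / 72.0 * k1I + 1.0 / 12.0 * k2I +
                           1.0 / 9.0 * k3I - 1.0 / 8.0 * k4I);
    double errX = h_try * (-5.0 / 72.0 * k1X + 1.0 / 12.0 * k2X +
                           1.0 / 9.0 * k3X - 1.0 / 8.0 * k4X);
    double scI = abs_tol + rel_tol * std::max(std::fabs(I), std::fabs(In));
    double scX = abs_tol + rel_tol * std::max(std::fabs(X), std::fabs(Xn));
    double err = std::sqrt(0.5 * ((errI / scI) * (errI / scI) +
                                  (errX / scX) * (errX / scX)));

    if (!std::isfinite(err) || !std::isfinite(In) || !std::isfinite(Xn)) {
      status = 2; fail_t = t; break;
    }

    bool hit_break = false;
    if (err <= 1.0) {
      hit_break = next_break + 1 < breaks.size() &&
          std::fabs(tn - breaks[next_break]) <
              1e-9 * std::max(1.0, std::fabs(tn));
      H.ts.push_back(t);   H.te.push_back(tn);
      H.I0.push_back(I);   H.I1.push_back(In);
      H.dI0.push_back(k1I); H.dI1.push_back(k4I);
      H.X0.push_back(X);   H.X1.push_back(Xn);
      H.dX0.push_back(k1X); H.dX1.push_back(k4X);
      t = tn; I = In; X = Xn;
      k1I = k4I; k1X = k4X;  // FSAL
    }
    double fac = (err <= 1e-12) ? 5.0 : 0.9 * std::pow(err, -1.0 / 3.0);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h = h_try * fac;
    // the delayed term's derivative jumps at break points; restart small so
    // the dense output resolves the post-kink ramp
    if (hit_break) h = initial_step > 0 ? initial_step : 1e-2;
    if (h > hmax) h = hmax;
  }

  // dense evaluation at report times (only over the newly added segments)
  int n_rep = report_times.size();
  NumericVector rep_I(n_rep), rep_X(n_rep);
  size_t k = first_new_seg;
  for (int i = 0; i < n_rep; ++i) {
    double rt = report_times[i];
    if (status != 0 && rt > t) { rep_I[i] = NA_REAL; rep_X[i] = NA_REAL; continue; }
    if (H.ts.empty() || rt <= t0) { rep_I[i] = y0[0]; rep_X[i] = y0[1]; continue; }
    if (rt >= t) { rep_I[i] = I; rep_X[i] = X; continue; }
    while (k < H.te.size() - 1 && H.te[k] < rt) ++k;
    double hs = H.te[k] - H.ts[k];
    if (hs <= 0.0) { rep_I[i] = H.I1[k]; rep_X[i] = H.X1[k]; continue; }
    double th = (rt - H.ts[k]) / hs;
    rep_I[i] = hermite(th, hs, H.I0[k], H.I1[k], H.dI0[k], H.dI1[k]);
    rep_X[i] = hermite(th, hs, H.X0[k], H.X1[k], H.dX0[k], H.dX1[k]);
  }

  return List::create(
      _["t_end"] = t, _["I_end"] = I, _["X_end"] = X,
      _["status"] = status, _["fail_t"] = fail_t,
      _["n_steps"] = (double)nsteps,
      _["history"] = List::create(
          _["ts"] = wrap(H.ts), _["te"] = wrap(H.te),
          _["I0"] = wrap(H.I0), _["I1"] = wrap(H.I1),
          _["dI0"] = wrap(H.dI0), _["dI1"] = wrap(H.dI1),
          _["X0"] = wrap(H.X0), _["X1"] = wrap(H.X1),
          _["dX0"] = wrap(H.dX0), _["dX1"] = wrap(H.dX1),
          _["pre_I"] = H.pre_I, _["t_min"] = H.t_min),
      _["rep_I"] = rep_I, _["rep_X"] = rep_X);
}
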