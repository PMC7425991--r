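// Numerical core: reaction-network evaluation (rates, drift, Jacobian,
// diffusion), adaptive Dormand-Prince 5(4) integration of the macroscopic
// ODE and of the LNA covariance/fundamental-matrix system, and the direct
// Gillespie SSA (optionally driven by an externally imposed core path).
//
// Networks arrive as a flat numeric encoding built in R (see encode_network()
// in R/network.R). Rates are evaluated on the concentration scale:
//   f_j(x, t) = theta[k_j] * prod_f phi_f
// with factors phi of three kinds:
//   type 1: v^n            (mass-action power)
//   type 2: v^h/(v^h+K^h)  (Hill activation)
//   type 3: K^h/(v^h+K^h)  (Hill repression)
// and factor source v one of: a species (or sum of two species), the
// time-gated dose parameter, or a plain parameter. Copy-number propensities
// are Omega * f(X/Omega, t) (density-dependent family).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  arma::mat S;          // d x m stoichiometry
  arma::ivec reac_k;    // m, 1-based parameter index of rate constant
  arma::mat factors;    // nf x 6: reac, type, s1, s2, kidx, hexp
  int dose_idx;         // 1-based param index of dose, 0 if none
  arma::mat windows;    // 2 x nw stimulation windows [start; end)
  int d, m, nf;
};

Net parse_net(const List& net) {
  Net N;
  N.S = as<arma::mat>(net["stoich"]);
  N.reac_k = as<arma::ivec>(net["reac_k"]);
  N.factors = as<arma::mat>(net["factors"]);
  N.dose_idx = as<int>(net["dose_idx"]);
  N.windows = as<arma::mat>(net["windows"]);
  N.d = N.S.n_rows;
  N.m = N.S.n_cols;
  N.nf = N.factors.n_rows;
  return N;
}

inline bool dose_on(const Net& N, double t) {
  for (arma::uword w = 0; w < N.windows.n_cols; ++w)
    if (t >= N.windows(0, w) && t < N.windows(1, w)) return true;
  return false;
}

// factor value, d(value)/dv, and source value v with d(v)/dx_i = 1 for
// i in {s1, s2} when the source is a species.
struct FactVal { double phi; double dphi_dv; int s1; int s2; };

inline FactVal eval_factor(const Net& N, const arma::vec& theta,
                           const arma::vec& x, double t, int f) {
  FactVal out; out.s1 = -1; out.s2 = -1;
  const int type = (int)N.factors(f, 1);
  const int s1 = (int)N.factors(f, 2);
  const int s2 = (int)N.factors(f, 3);
  const int kidx = (int)N.factors(f, 4);
  const double h = N.factors(f, 5);
  double v;
  if (s1 > 0) {
    v = x(s1 - 1); out.s1 = s1 - 1;
    if (s2 > 0) { v += x(s2 - 1); out.s2 = s2 - 1; }
  } else if (s1 == 0) {
    v = dose_on(N, t) ? theta(N.dose_idx - 1) : 0.0;
  } else { // parameter source
    v = theta(-s1 - 1);
  }
  if (v < 0.0) v = 0.0; // clamp: propensities vanish outside the orthant
  if (type == 1) {
    out.phi = std::pow(v, h);
    out.dphi_dv = (h == 1.0) ? 1.0 : h * std::pow(v, h - 1.0);
  } else {
    const double K = theta(kidx - 1);
    const double vh = std::pow(v, h), Kh = std::pow(K, h);
    const double den = vh + Kh;
    if (den <= 0.0) { out.phi = (type == 3) ? 1.0 : 0.0; out.dphi_dv = 0.0; return out; }
    if (type == 2) out.phi = vh / den; else out.phi = Kh / den;
    double dv = h * ((v > 0) ? std::pow(v, h - 1.0) : (h == 1.0 ? 1.0 : 0.0)) * Kh / (den * den);
    out.dphi_dv = (type == 2) ? dv : -dv;
  }
  return out;
}

// rate vector f (m), optionally also df/dx (m x d)
void eval_rates(const Net& N, const arma::vec& theta, const arma::vec& x,
                double t, arma::vec& f, arma::mat* dfdx) {
  f.set_size(N.m);
  for (int j = 0; j < N.m; ++j) f(j) = theta(N.reac_k(j) - 1);
  if (dfdx) dfdx->zeros(N.m, N.d);
  // factor values per reaction; derivative via product rule
  std::vector<std::vector<FactVal>> fv(N.m);
  for (int k = 0; k < N.nf; ++k) {
    int j = (int)N.factors(k, 0) - 1;
    FactVal v = eval_factor(N, theta, x, t, k);
    f(j) *= v.phi;
    if (dfdx) fv[j].push_back(v);
  }
  if (dfdx) {
    for (int j = 0; j < N.m; ++j) {
      const double kconst = theta(N.reac_k(j) - 1);
      const size_t nf = fv[j].size();
      for (size_t a = 0; a < nf; ++a) {
        const FactVal& va = fv[j][a];
        if (va.s1 < 0 || va.dphi_dv == 0.0) continue;
        double prod = kconst * va.dphi_dv;
        for (size_t b = 0; b < nf; ++b) if (b != a) prod *= fv[j][b].phi;
        (*dfdx)(j, va.s1) += prod;
        if (va.s2 >= 0) (*dfdx)(j, va.s2) += prod;
      }
    }
  }
}

// Dormand-Prince 5(4) adaptive step over [t0, t1] for a generic RHS.
template <typename RHS>
void dp45(RHS rhs, arma::vec& y, double t0, double t1,
          double rtol, double atol) {
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
  if (t1 <= t0) return;
  double t = t0;
  double h = std::min(1.0, (t1 - t0) / 10.0);
  const int n = y.n_elem;
  arma::vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), yt(n), ynew(n), err(n);
  rhs(t, y, k1);
  int nsteps = 0;
  while (t < t1) {
    if (++nsteps > 2000000) stop("ODE integration failed: step limit reached at t=%f", t);
    if (h > t1 - t) h = t1 - t;
    yt = y + h * a21 * k1; rhs(t + c2 * h, yt, k2);
    yt = y + h * (a31 * k1 + a32 * k2); rhs(t + c3 * h, yt, k3);
    yt = y + h * (a41 * k1 + a42 * k2 + a43 * k3); rhs(t + c4 * h, yt, k4);
    yt = y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4); rhs(t + c5 * h, yt, k5);
    yt = y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    rhs(t + h, yt, k6);
    ynew = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    rhs(t + h, ynew, k7);
    err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    double enorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::abs(y(i)), std::abs(ynew(i)));
      double r = err(i) / sc;
      enorm += r * r;
    }
    enorm = std::sqrt(enorm / n);
    if (enorm <= 1.0) {
      t += h; y = ynew; k1 = k7;
      double fac = (enorm > 1e-12) ? 0.9 * std::pow(enorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(enorm, -0.2));
      if (h < 1e-12 * (t1 - t0))
        stop("ODE integration failed: step size underflow at t=%f", t);
    }
  }
}

// breakpoints (window edges) inside (t0, t1), sorted, plus t1
std::vector<double> segment_stops(const Net& N, double t0, double t1) {
  std::vector<double> s;
  for (arma::uword w = 0; w < N.windows.n_cols; ++w) {
    for (int r = 0; r < 2; ++r) {
      double e = N.windows(r, w);
      if (e > t0 && e < t1) s.push_back(e);
    }
  }
  s.push_back(t1);
  std::sort(s.begin(), s.end());
  s.erase(std::unique(s.begin(), s.end()), s.end());
  return s;
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_rates(List net, arma::vec theta, arma::vec x, double t) {
  Net N = parse_net(net);
  arma::vec f;
  eval_rates(N, theta, x, t, f, nullptr);
  return f;
}

// [[Rcpp::export]]
List cpp_drift_jac(List net, arma::vec theta, arma::vec x, double t) {
  Net N = parse_net(net);
  arma::vec f; arma::mat dfdx;
  eval_rates(N, theta, x, t, f, &dfdx);
  arma::vec F = N.S * f;
  arma::mat J = N.S * dfdx;
  arma::mat D = N.S * arma::diagmat(f) * N.S.t();
  return List::create(_["F"] = F, _["J"] = J, _["D"] = D, _["f"] = f);
}

// [[Rcpp::export]]
arma::mat cpp_ode(List net, arma::vec theta, arma::vec x0, arma::vec times,
                  double rtol = 1e-8, double atol = 1e-10) {
  Net N = parse_net(net);
  const int q = times.n_elem;
  arma::mat out(q, N.d);
  arma::vec y = x0;
  double t = times(0);
  out.row(0) = y.t();
  auto rhs = [&](double tt, const arma::vec& yy, arma::vec& dy) {
    arma::vec f;
    eval_rates(N, theta, yy, tt, f, nullptr);
    dy = N.S * f;
  };
  for (int k = 1; k < q; ++k) {
    for (double stop_t : segment_stops(N, t, times(k))) {
      dp45(rhs, y, t, stop_t, rtol, atol);
      t = stop_t;
    }
    out.row(k) = y.t();
  }
  return out;
}

// LNA pieces per observation interval: state x_k, flow F_k, fundamental
// matrix Phi_k (from previous obs time) and process-noise integral Q_k
// (covariance accumulated from zero over the interval, concentration scale).
// [[Rcpp::export]]
List cpp_lna(List net, arma::vec theta, arma::vec x0, double t0,
             arma::vec obstimes, double omega,
             double rtol = 1e-6, double atol = 1e-9) {
  Net N = parse_net(net);
  const int d = N.d, q = obstimes.n_elem;
  arma::mat xs(q, d), Fs(q, d);
  List Phis(q), Qs(q);
  // augmented state: x (d), Phi (d*d col-major), Q (d*d)
  auto rhs = [&](double tt, const arma::vec& yy, arma::vec& dy) {
    arma::vec x = yy.subvec(0, d - 1);
    arma::mat Phi(const_cast<double*>(yy.memptr()) + d, d, d, false, true);
    arma::mat Q(const_cast<double*>(yy.memptr()) + d + d * d, d, d, false, true);
    arma::vec f; arma::mat dfdx;
    eval_rates(N, theta, x, tt, f, &dfdx);
    arma::mat J = N.S * dfdx;
    arma::mat D = N.S * arma::diagmat(f) * N.S.t();
    dy.set_size(yy.n_elem);
    dy.subvec(0, d - 1) = N.S * f;
    arma::mat dPhi = J * Phi;
    arma::mat dQ = J * Q + Q * J.t() + D / omega;
    std::copy(dPhi.memptr(), dPhi.memptr() + d * d, dy.memptr() + d);
    std::copy(dQ.memptr(), dQ.memptr() + d * d, dy.memptr() + d + d * d);
  };
  arma::vec x = x0;
  double t = t0;
  for (int k = 0; k < q; ++k) {
    arma::vec y(d + 2 * d * d, arma::fill::zeros);
    y.subvec(0, d - 1) = x;
    arma::mat I = arma::eye(d, d);
    std::copy(I.memptr(), I.memptr() + d * d, y.memptr() + d);
    for (double stop_t : segment_stops(N, t, obstimes(k))) {
      dp45(rhs, y, t, stop_t, rtol, atol);
      t = stop_t;
    }
    x = y.subvec(0, d - 1);
    arma::mat Phi(y.memptr() + d, d, d);
    arma::mat Q(y.memptr() + d + d * d, d, d);
    Q = 0.5 * (Q + Q.t());
    arma::vec f;
    eval_rates(N, theta, x, obstimes(k), f, nullptr);
    xs.row(k) = x.t();
    Fs.row(k) = (N.S * f).t();
    Phis[k] = Phi;
    Qs[k] = Q;
  }
  return List::create(_["xs"] = xs, _["Fs"] = Fs, _["Phi"] = Phis, _["Q"] = Qs);
}

// Direct-method SSA on copy numbers; records the state at each record time
// (value immediately before that time). Uses R's RNG (honours set.seed()).
// [[Rcpp::export]]
arma::mat cpp_ssa(List net, arma::vec theta, arma::vec x0counts, double t0,
                  arma::vec record_times, double omega,
                  double max_events = 5e8) {
  Net N = parse_net(net);
  RNGScope scope;
  const int d = N.d, q = record_times.n_elem;
  arma::mat out(q, d);
  arma::vec X = x0counts;
  double t = t0, tmax = record_times(q - 1);
  int rec = 0;
  double nev = 0;
  std::vector<double> stops = segment_stops(N, t0, tmax + 1e-9);
  size_t si = 0;
  arma::vec f(N.m);
  while (rec < q) {
    double tstop = tmax + 1e-9;
    while (si < stops.size() && stops[si] <= t) ++si;
    if (si < stops.size()) tstop = std::min(tstop, stops[si]);
    eval_rates(N, theta, X / omega, t, f, nullptr);
    double a0 = 0.0;
    for (int j = 0; j < N.m; ++j) a0 += std::max(0.0, f(j));
    a0 *= omega;
    if (!std::isfinite(a0)) stop("SSA propensity overflow at t=%f", t);
    double tnext = (a0 > 0) ? t + R::exp_rand() / a0 : std::numeric_limits<double>::infinity();
    if (tnext >= tstop) {
      // no event before the stop: flush records in [t, tstop), move to stop
      while (rec < q && record_times(rec) <= tstop) { out.row(rec) = X.t(); ++rec; }
      t = tstop;
      if (t > tmax) break;
      continue;
    }
    while (rec < q && record_times(rec) <= tnext) { out.row(rec) = X.t(); ++rec; }
    t = tnext;
    // choose reaction
    double u = R::unif_rand() * a0 / omega, acc = 0.0;
    int j = N.m - 1;
    for (int jj = 0; jj < N.m; ++jj) {
      acc += std::max(0.0, f(jj));
      if (u <= acc) { j = jj; break; }
    }
    X += N.S.col(j);
    for (int i = 0; i < d; ++i) if (X(i) < 0) X(i) = 0;
    if (++nev > max_events) stop("SSA event budget exceeded at t=%f", t);
  }
  return out;
}

// SSA for a gene module driven by an imposed core path. Species listed in
// driver_idx (1-based) are overwritten from the piecewise path (concentration
// scale, linear interpolation refreshed on the driver grid); their stoich
// rows must be zero. Propensities are frozen between successive driver grid
// times (exact SSA within each subinterval).
// [[Rcpp::export]]
arma::mat cpp_ssa_driven(List net, arma::vec theta, arma::vec x0counts,
                         arma::ivec driver_idx, arma::vec driver_times,
                         arma::mat driver_states, arma::vec record_times,
                         double omega, double max_events = 5e8) {
  Net N = parse_net(net);
  RNGScope scope;
  const int d = N.d, q = record_times.n_elem, ng = driver_times.n_elem;
  arma::mat out(q, d);
  arma::vec X = x0counts;
  int rec = 0;
  double nev = 0;
  arma::vec f(N.m);
  for (int g = 0; g < ng - 1 && rec < q; ++g) {
    double t = driver_times(g), tend = driver_times(g + 1);
    // impose driver values (counts) at interval start
    for (arma::uword a = 0; a < driver_idx.n_elem; ++a)
      X(driver_idx(a) - 1) = driver_states(g, a) * omega;
    while (t < tend && rec < q) {
      eval_rates(N, theta, X / omega, t, f, nullptr);
      double a0 = 0.0;
      for (int j = 0; j < N.m; ++j) a0 += std::max(0.0, f(j));
      a0 *= omega;
      double tnext = (a0 > 0) ? t + R::exp_rand() / a0 : std::numeric_limits<double>::infinity();
      if (tnext >= tend) {
        while (rec < q && record_times(rec) <= tend) { out.row(rec) = X.t(); ++rec; }
        break;
      }
      while (rec < q && record_times(rec) <= tnext) { out.row(rec) = X.t(); ++rec; }
      t = tnext;
      double u = R::unif_rand() * a0 / omega, acc = 0.0;
      int j = N.m - 1;
      for (int jj = 0; jj < N.m; ++jj) {
        acc += std::max(0.0, f(jj));
        if (u <= acc) { j = jj; break; }
      }
      X += N.S.col(j);
      for (int i = 0; i < d; ++i) if (X(i) < 0) X(i) = 0;
      if (++nev > max_events) stop("SSA event budget exceeded at t=%f", t);
    }
  }
  while (rec < q) { out.row(rec) = X.t(); ++rec; }
  return out;
}
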