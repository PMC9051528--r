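// Forward solvers for the two-compartment exchange model (2CXM)
//
//   vp dCp/dt = Fp (CAIF - Cp) + PS (Ce - Cp)
//   ve dCe/dt = PS (Cp - Ce)
//   Cmyo      = vp Cp + ve Ce
//
// The AIF is supplied as samples on the output grid and treated as
// piecewise linear in between.  The "exact" path propagates the state with
// the matrix exponential of an augmented linear system, which integrates a
// linear ODE with piecewise-linear forcing without truncation error and is
// unconditionally stable (the system becomes very stiff for small vp).
// The "rk4" path is a classical fixed-step integrator on a refined grid,
// kept as an independent numerical cross-check.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

static void check_params(double Fp, double vp, double ve, double PS) {
  if (!std::isfinite(Fp) || !std::isfinite(vp) || !std::isfinite(ve) ||
      !std::isfinite(PS))
    Rcpp::stop("kinetic parameters must be finite");
  if (Fp < 0.0 || PS < 0.0) Rcpp::stop("Fp and PS must be non-negative");
  if (vp <= 0.0 || ve <= 0.0)
    Rcpp::stop("vp = 0 or ve = 0 makes the 2CXM singular");
}

static mat system_matrix(double Fp, double vp, double ve, double PS) {
  mat A(2, 2);
  A(0, 0) = -(Fp + PS) / vp;
  A(0, 1) = PS / vp;
  A(1, 0) = PS / ve;
  A(1, 1) = -PS / ve;
  return A;
}

// Propagator for one step of length h: the augmented state
// w = (Cp, Ce, f1, f2, s1, s2) with f the forcing at step start and s its
// slope obeys w' = M w, so x(h) depends linearly on (x0, f0, (f1-f0)/h).
static mat step_propagator(const mat& A, double h) {
  mat M(6, 6, arma::fill::zeros);
  M.submat(0, 0, 1, 1) = A;
  M(0, 2) = 1.0; M(1, 3) = 1.0;
  M(2, 4) = 1.0; M(3, 5) = 1.0;
  return arma::expmat(M * h);
}

// Exact propagation; returns N x 2 matrix (Cp, Ce).
static mat solve_exact(double Fp, double vp, double ve, double PS,
                       const vec& t, const vec& aif) {
  const arma::uword N = t.n_elem;
  mat out(N, 2, arma::fill::zeros);
  mat A = system_matrix(Fp, vp, ve, PS);
  double h_cached = -1.0;
  mat Phi;
  vec w(6, arma::fill::zeros), x(2, arma::fill::zeros);
  const double fscale = Fp / vp;
  for (arma::uword n = 0; n + 1 < N; ++n) {
    const double h = t(n + 1) - t(n);
    if (h_cached < 0.0 || std::abs(h - h_cached) > 1e-12 * h) {
      Phi = step_propagator(A, h);
      h_cached = h;
    }
    const double f0 = fscale * aif(n);
    const double f1 = fscale * aif(n + 1);
    w(0) = x(0); w(1) = x(1);
    w(2) = f0;   w(3) = 0.0;
    w(4) = (f1 - f0) / h; w(5) = 0.0;
    x = Phi.rows(0, 1) * w;
    out(n + 1, 0) = x(0);
    out(n + 1, 1) = x(1);
  }
  return out;
}

// RK4 on a refined grid; substep count grows with the fastest rate so the
// integrator stays inside its stability region.
static mat solve_rk4(double Fp, double vp, double ve, double PS,
                     const vec& t, const vec& aif, int refine) {
  const arma::uword N = t.n_elem;
  mat out(N, 2, arma::fill::zeros);
  double cp = 0.0, ce = 0.0;
  const double rate = (Fp + PS) / vp + PS / ve;
  for (arma::uword n = 0; n + 1 < N; ++n) {
    const double h = t(n + 1) - t(n);
    int ns = refine;
    const int stab = (int)std::ceil(2.0 * h * rate);
    if (stab > ns) ns = stab;
    if (ns > 4000) ns = 4000;
    const double hs = h / ns;
    const double a0 = aif(n), a1 = aif(n + 1);
    for (int s = 0; s < ns; ++s) {
      // AIF is piecewise linear; sample it at the RK4 stage times
      const double u0 = (double)s / ns, u1 = (s + 0.5) / ns, u2 = (s + 1.0) / ns;
      const double ca0 = a0 + (a1 - a0) * u0;
      const double cam = a0 + (a1 - a0) * u1;
      const double ca1 = a0 + (a1 - a0) * u2;
      auto fcp = [&](double p, double e, double ca) {
        return (Fp * (ca - p) + PS * (e - p)) / vp;
      };
      auto fce = [&](double p, double e) { return PS * (p - e) / ve; };
      const double k1p = fcp(cp, ce, ca0),           k1e = fce(cp, ce);
      const double k2p = fcp(cp + 0.5 * hs * k1p, ce + 0.5 * hs * k1e, cam);
      const double k2e = fce(cp + 0.5 * hs * k1p, ce + 0.5 * hs * k1e);
      const double k3p = fcp(cp + 0.5 * hs * k2p, ce + 0.5 * hs * k2e, cam);
      const double k3e = fce(cp + 0.5 * hs * k2p, ce + 0.5 * hs * k2e);
      const double k4p = fcp(cp + hs * k3p, ce + hs * k3e, ca1);
      const double k4e = fce(cp + hs * k3p, ce + hs * k3e);
      cp += hs / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
      ce += hs / 6.0 * (k1e + 2.0 * k2e + 2.0 * k3e + k4e);
    }
    out(n + 1, 0) = cp;
    out(n + 1, 1) = ce;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cxm_solve_cpp(Rcpp::NumericVector params, arma::vec t, arma::vec aif,
                        int method, int refine) {
  const double Fp = params[0], vp = params[1], ve = params[2], PS = params[3];
  check_params(Fp, vp, ve, PS);
  if (t.n_elem != aif.n_elem) Rcpp::stop("aif length must match time grid");
  if (!aif.is_finite()) Rcpp::stop("AIF contains non-finite values");
  if (t.n_elem < 2) Rcpp::stop("time grid needs at least two points");
  for (arma::uword i = 1; i < t.n_elem; ++i)
    if (t(i) <= t(i - 1)) Rcpp::stop("time grid must be strictly increasing");
  if (method == 0) return solve_exact(Fp, vp, ve, PS, t, aif);
  return solve_rk4(Fp, vp, ve, PS, t, aif, refine);
}

// Tissue curve only, for many parameter sets (K x 4 matrix) at once.
// [[Rcpp::export]]
arma::mat cxm_cmyo_many_cpp(arma::mat P, arma::vec t, arma::vec aif) {
  const arma::uword K = P.n_rows;
  arma::mat out(K, t.n_elem);
  for (arma::uword k = 0; k < K; ++k) {
    const double Fp = P(k, 0), vp = P(k, 1), ve = P(k, 2), PS = P(k, 3);
    check_params(Fp, vp, ve, PS);
    mat sol = solve_exact(Fp, vp, ve, PS, t, aif);
    out.row(k) = (vp * sol.col(0) + ve * sol.col(1)).t();
  }
  return out;
}

// Sum of squared differences between the model tissue curve and an observed
// curve; objective for the NLLS baseline.  Non-finite model output (wild
// trial parameters) returns a large penalty instead of propagating NaN.
// [[Rcpp::export]]
double cxm_sse_cpp(Rcpp::NumericVector params, arma::vec t, arma::vec aif,
                   arma::vec curve) {
  const double Fp = params[0], vp = params[1], ve = params[2], PS = params[3];
  if (vp <= 0.0 || ve <= 0.0 || Fp < 0.0 || PS < 0.0) return 1e12;
  mat sol = solve_exact(Fp, vp, ve, PS, t, aif);
  vec cm = vp * sol.col(0) + ve * sol.col(1);
  if (!cm.is_finite()) return 1e12;
  const vec d = cm - curve;
  return arma::dot(d, d);
}

// Central-difference gradient of the SSE objective, computed entirely in
// compiled code (the objective involves an ODE solve, so analytic
// gradients are not available; one call here replaces eight R-level
// objective evaluations inside the optimiser).
// [[Rcpp::export]]
arma::vec cxm_sse_grad_cpp(Rcpp::NumericVector params, arma::vec t,
                           arma::vec aif, arma::vec curve, double rel_h) {
  arma::vec g(4);
  Rcpp::NumericVector p = Rcpp::clone(params);
  for (int j = 0; j < 4; ++j) {
    const double h = rel_h * std::max(std::abs(p[j]), 1e-3);
    const double orig = p[j];
    p[j] = orig + h;
    const double up = cxm_sse_cpp(p, t, aif, curve);
    p[j] = orig - h;
    const double dn = cxm_sse_cpp(p, t, aif, curve);
    p[j] = orig;
    g(j) = (up - dn) / (2.0 * h);
  }
  return g;
}
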