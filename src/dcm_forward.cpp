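// Forward model for the bilinear DCM: neural states advance by an exact
// matrix-exponential step (inputs are piecewise constant on the microtime
// grid), hemodynamics by RK4 of the balloon model with z held constant
// over each step.  Input rows are grouped into unique patterns so the
// expensive operators (matrix exponentials) are built once per pattern.

#include <RcppArmadillo.h>
#include <map>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct InputPatterns {
  std::vector<unsigned> id;  // pattern index per time step
  mat rows;                  // unique input rows (n_pattern x m)
};

InputPatterns find_patterns(const mat& u) {
  InputPatterns out;
  out.id.resize(u.n_rows);
  std::map<std::vector<double>, unsigned> seen;
  std::vector<unsigned> order;
  for (uword t = 0; t < u.n_rows; ++t) {
    std::vector<double> key(u.n_cols);
    for (uword k = 0; k < u.n_cols; ++k) key[k] = u(t, k);
    auto it = seen.find(key);
    if (it == seen.end()) {
      unsigned idx = seen.size();
      seen.emplace(std::move(key), idx);
      out.id[t] = idx;
      order.push_back(t);
    } else {
      out.id[t] = it->second;
    }
  }
  out.rows.set_size(order.size(), u.n_cols);
  for (size_t p = 0; p < order.size(); ++p) out.rows.row(p) = u.row(order[p]);
  return out;
}

// Per-pattern step operators: z(t+dt) = E z(t) + w.
struct StepOps {
  std::vector<mat> E;
  std::vector<vec> w;
};

StepOps build_ops(const mat& A, const cube& B, const mat& C, double dt,
                  const InputPatterns& pat) {
  StepOps ops;
  const uword n = A.n_rows;
  for (uword p = 0; p < pat.rows.n_rows; ++p) {
    mat J = A;
    for (uword k = 0; k < B.n_slices && k < pat.rows.n_cols; ++k)
      if (pat.rows(p, k) != 0.0) J += pat.rows(p, k) * B.slice(k);
    mat E = expmat(J * dt);
    mat rhs = (E - eye(n, n)) * C;
    mat W;
    if (!solve(W, J, rhs)) W = dt * C;  // singular J: first-order fallback
    ops.E.push_back(E);
    ops.w.push_back(W * pat.rows.row(p).t());
  }
  return ops;
}

mat integrate_with_ops(const StepOps& ops, const InputPatterns& pat,
                       uword n, const vec& z0) {
  const uword nt = pat.id.size();
  mat z(nt, n);
  vec zc = z0;
  z.row(0) = zc.t();
  for (uword t = 0; t + 1 < nt; ++t) {
    const unsigned p = pat.id[t];
    zc = ops.E[p] * zc + ops.w[p];
    if (!zc.is_finite() || norm(zc, "inf") > 1e6) {
      z.rows(t + 1, nt - 1).fill(datum::nan);
      return z;
    }
    z.row(t + 1) = zc.t();
  }
  return z;
}

// Balloon-model derivatives for all nodes; state rows: s, f, v, q.
inline void hemo_deriv(const mat& st, const rowvec& z, double kappa,
                       double gam, double tau, double alpha, double E0,
                       mat& d) {
  const double ia = 1.0 / alpha;
  for (uword j = 0; j < st.n_cols; ++j) {
    double s = st(0, j), f = st(1, j), v = st(2, j), q = st(3, j);
    if (f < 1e-6) f = 1e-6;
    if (v < 1e-6) v = 1e-6;
    double fv = std::pow(v, ia);
    double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f);
    d(0, j) = z(j) - kappa * s - gam * (f - 1.0);
    d(1, j) = s;
    d(2, j) = (f - fv) / tau;
    d(3, j) = (f * Ef / E0 - fv * q / v) / tau;
  }
}

mat hemo_integrate(const mat& z, double dt, double kappa, double gam,
                   double tau, double alpha, double E0, double V0) {
  const uword nt = z.n_rows, n = z.n_cols;
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  mat st(4, n);
  st.row(0).zeros();
  st.row(1).ones();
  st.row(2).ones();
  st.row(3).ones();
  mat y(nt, n);
  mat d1(4, n), d2(4, n), d3(4, n), d4(4, n), tmp(4, n);
  for (uword t = 0; t < nt; ++t) {
    for (uword j = 0; j < n; ++j) {
      double v = st(2, j), q = st(3, j);
      y(t, j) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
    if (t + 1 == nt) break;
    rowvec zr = z.row(t);
    if (!zr.is_finite()) {
      y.rows(t + 1, nt - 1).fill(datum::nan);
      return y;
    }
    hemo_deriv(st, zr, kappa, gam, tau, alpha, E0, d1);
    tmp = st + 0.5 * dt * d1;
    hemo_deriv(tmp, zr, kappa, gam, tau, alpha, E0, d2);
    tmp = st + 0.5 * dt * d2;
    hemo_deriv(tmp, zr, kappa, gam, tau, alpha, E0, d3);
    tmp = st + dt * d3;
    hemo_deriv(tmp, zr, kappa, gam, tau, alpha, E0, d4);
    st += (dt / 6.0) * (d1 + 2.0 * d2 + 2.0 * d3 + d4);
    if (!st.is_finite()) {
      y.rows(t + 1, nt - 1).fill(datum::nan);
      return y;
    }
  }
  return y;
}

mat sample_rows(const mat& y, const uvec& scan_idx) {
  mat out(scan_idx.n_elem, y.n_cols);
  for (uword i = 0; i < scan_idx.n_elem; ++i)
    out.row(i) = y.row(scan_idx(i) - 1);  // 1-based indices from R
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_integrate_neural(const arma::mat& A, const arma::cube& B,
                               const arma::mat& C, const arma::mat& u,
                               double dt, const arma::vec& z0) {
  InputPatterns pat = find_patterns(u);
  StepOps ops = build_ops(A, B, C, dt, pat);
  return integrate_with_ops(ops, pat, A.n_rows, z0);
}

// [[Rcpp::export]]
arma::mat cpp_hemo_forward(const arma::mat& z, double dt, double kappa,
                           double gam, double tau, double alpha, double E0,
                           double V0) {
  return hemo_integrate(z, dt, kappa, gam, tau, alpha, E0, V0);
}

// [[Rcpp::export]]
arma::mat cpp_dcm_forward(const arma::mat& A, const arma::cube& B,
                          const arma::mat& C, const arma::mat& u, double dt,
                          double kappa, double gam, double tau, double alpha,
                          double E0, double V0,
                          const arma::uvec& scan_idx) {
  mat z = cpp_integrate_neural(A, B, C, u, dt, zeros<vec>(A.n_rows));
  mat y = hemo_integrate(z, dt, kappa, gam, tau, alpha, E0, V0);
  return sample_rows(y, scan_idx);
}

// Batched forward passes sharing one input grid: used for finite-difference
// Jacobians during inversion.  `models` is a list of list(A, B, C); the
// input-pattern decomposition is computed once and shared.
// [[Rcpp::export]]
arma::cube cpp_dcm_forward_many(Rcpp::List models, const arma::mat& u,
                                double dt, double kappa, double gam,
                                double tau, double alpha, double E0,
                                double V0, const arma::uvec& scan_idx) {
  const int K = models.size();
  InputPatterns pat = find_patterns(u);
  cube out;
  for (int k = 0; k < K; ++k) {
    Rcpp::List m = models[k];
    mat A = Rcpp::as<mat>(m["A"]);
    cube B = Rcpp::as<cube>(m["B"]);
    mat C = Rcpp::as<mat>(m["C"]);
    StepOps ops = build_ops(A, B, C, dt, pat);
    mat z = integrate_with_ops(ops, pat, A.n_rows, zeros<vec>(A.n_rows));
    mat y = hemo_integrate(z, dt, kappa, gam, tau, alpha, E0, V0);
    mat ys = sample_rows(y, scan_idx);
    if (k == 0) out.set_size(ys.n_rows, ys.n_cols, K);
    out.slice(k) = ys;
  }
  return out;
}
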