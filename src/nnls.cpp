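#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set NNLS for one right-hand side.
// Solves min ||S a - b||_2 subject to a >= 0.
// S is C x K with K small (spectral endmembers); tol is the KKT tolerance
// on the dual vector w = S'(b - S a).
static vec nnls_one(const mat& S, const vec& b, double tol, int max_iter) {
  const uword K = S.n_cols;
  vec a(K, fill::zeros);
  uvec passive(K, fill::zeros);          // 1 = in passive (free) set
  vec w = S.t() * b;                     // gradient at a = 0

  int iter = 0;
  while (iter++ < max_iter) {
    // most violating zero-constrained coordinate
    double wmax = 0.0; sword t = -1;
    for (uword j = 0; j < K; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0 || wmax <= tol) break;     // KKT satisfied
    passive(t) = 1;

    // inner loop: solve on the passive set, step back if infeasible
    for (;;) {
      uvec P = find(passive == 1);
      vec z;
      if (!solve(z, S.cols(P), b, solve_opts::fast)) {
        // rank-deficient passive set: fall back to minimum-norm solution
        z = pinv(S.cols(P)) * b;
      }
      if (z.min() > 0) {
        a.zeros();
        a(P) = z;
        break;
      }
      // feasible step towards z
      double alpha = datum::inf;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (z(i) <= 0) {
          double step = a(P(i)) / (a(P(i)) - z(i));
          if (step < alpha) alpha = step;
        }
      }
      for (uword i = 0; i < P.n_elem; ++i)
        a(P(i)) += alpha * (z(i) - a(P(i)));
      for (uword i = 0; i < P.n_elem; ++i)
        if (a(P(i)) <= tol) { passive(P(i)) = 0; a(P(i)) = 0; }
    }
    w = S.t() * (b - S * a);
  }
  return a;
}

// [[Rcpp::export]]
Rcpp::NumericVector nnls_cpp(const arma::mat& S, const arma::vec& b,
                             double tol = 1e-10, int max_iter = 200) {
  vec a = nnls_one(S, b, tol, max_iter);
  return Rcpp::wrap(a);
}

// Unmix a whole pixel matrix (pixels in rows). Returns n x (K + 1):
// K abundances followed by the residual 2-norm per pixel.
// [[Rcpp::export]]
Rcpp::NumericMatrix nnls_matrix_cpp(const arma::mat& S, const arma::mat& B,
                                    double tol = 1e-10, int max_iter = 200) {
  const uword n = B.n_rows, K = S.n_cols;
  mat out(n, K + 1);
  // cheap path: unconstrained solution, accepted when already feasible
  mat StS = S.t() * S;
  mat U;
  if (!solve(U, StS, S.t() * B.t(), solve_opts::likely_sympd)) // K x n
    U.set_size(K, n), U.fill(-1.0);      // force the NNLS path per pixel
  for (uword i = 0; i < n; ++i) {
    vec b = B.row(i).t();
    vec a = U.col(i);
    if (a.min() < 0) a = nnls_one(S, b, tol, max_iter);
    out(i, span(0, K - 1)) = a.t();
    out(i, K) = norm(b - S * a, 2);
  }
  return Rcpp::wrap(out);
}
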