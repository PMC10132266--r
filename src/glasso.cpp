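// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani
// scheme): cycle over columns of the working covariance W, solving an L1
// penalized regression for each column by coordinate descent. The diagonal
// is NOT penalized, so diag(W) = diag(S) throughout and S = I yields
// Omega = I at any lambda.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda, double tol,
                      int max_iter, Rcpp::Nullable<Rcpp::NumericMatrix> W0,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B0) {
  const uword p = S.n_rows;
  if (p == 1) {
    mat omega(1, 1); omega(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("omega") = omega,
                              Rcpp::Named("W") = S,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true,
                              Rcpp::Named("gap") = 0.0);
  }
  mat W = W0.isNotNull() ? Rcpp::as<mat>(W0.get()) : mat(S);
  mat B = B0.isNotNull() ? Rcpp::as<mat>(B0.get()) : mat(p, p, fill::zeros);
  W.diag() = S.diag();  // unpenalized diagonal is fixed at S

  const double inner_tol = std::max(tol * 1e-2, 1e-10);
  const int inner_max = 1000;
  const double denom = p * (p - 1);

  bool converged = false;
  double change = datum::inf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat W_old = W;
    for (uword j = 0; j < p; ++j) {
      // index set without j
      uvec idx(p - 1);
      for (uword k = 0, m = 0; k < p; ++k) if (k != j) idx(m++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = B.col(j); beta = beta.elem(idx);

      for (int ii = 0; ii < inner_max; ++ii) {
        double delta = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double r = s12(k) - dot(W11.row(k), beta) + W11(k, k) * beta(k);
          double bnew = soft(r, lambda) / W11(k, k);
          delta = std::max(delta, std::fabs(bnew - beta(k)));
          beta(k) = bnew;
        }
        if (delta < inner_tol) break;
      }
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    change = accu(abs(W - W_old)) / denom;  // mean abs off-diagonal change
    if (change < tol) { converged = true; break; }
  }

  // Recover the precision matrix column-wise from the regression
  // coefficients; exact zeros in beta carry over to Omega.
  mat omega(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (uword k = 0, m = 0; k < p; ++k) if (k != j) idx(m++) = k;
    vec beta = B.col(j); beta = beta.elem(idx);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double o22 = 1.0 / (W(j, j) - dot(w12, beta));
    omega(j, j) = o22;
    for (uword k = 0; k < p - 1; ++k)
      omega(idx(k), j) = (beta(k) == 0.0) ? 0.0 : -beta(k) * o22;
  }
  // symmetrize; preserve the exact-zero support agreed by both columns
  mat omega_s = 0.5 * (omega + omega.t());
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (omega(i, j) == 0.0 && omega(j, i) == 0.0) {
        omega_s(i, j) = 0.0; omega_s(j, i) = 0.0;
      }

  return Rcpp::List::create(Rcpp::Named("omega") = omega_s,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("gap") = change);
}
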