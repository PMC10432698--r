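// Batched per-locus logistic regression for genome scans.
// Each locus fits y ~ [C, d_l] by IRLS, where C is the shared covariate
// design (including the intercept) and d_l the locus dosage column. Only
// the dosage term's estimate and Wald SE are returned; R decides status.
// Buffers are reused across loci; the null-model coefficients warm-start
// every fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List logistic_scan_cpp(const arma::vec& y, const arma::mat& D,
                             const arma::mat& C, const arma::vec& beta0,
                             int max_iter = 25, double tol = 1e-8) {
  const uword n = y.n_elem, L = D.n_cols, pc = C.n_cols, p = pc + 1;
  vec out_beta(L, fill::value(datum::nan));
  vec out_se(L, fill::value(datum::nan));
  ivec conv(L, fill::zeros);

  mat X(n, p);
  X.cols(0, pc - 1) = C;
  mat Xw(n, p);
  vec eta(n), mu(n), w(n), z(n), beta(p), beta_new(p), b(p);
  mat A(p, p), Ainv(p, p);

  for (uword l = 0; l < L; ++l) {
    X.col(pc) = D.col(l);
    beta.zeros();
    beta.subvec(0, pc - 1) = beta0;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      eta = X * beta;
      mu = 1.0 / (1.0 + exp(-eta));
      w = mu % (1.0 - mu);
      w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
      z = eta + (y - mu) / w;
      Xw = X.each_col() % w;
      A = X.t() * Xw;
      b = Xw.t() * z;
      if (!solve(beta_new, A, b, solve_opts::likely_sympd + solve_opts::no_approx))
        break;
      double step = max(abs(beta_new - beta));
      beta = beta_new;
      if (step < tol) {
        if (inv_sympd(Ainv, A)) {
          out_beta(l) = beta(pc);
          out_se(l) = std::sqrt(Ainv(pc, pc));
          ok = true;
        }
        break;
      }
    }
    conv(l) = ok ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = out_beta,
                            Rcpp::Named("se") = out_se,
                            Rcpp::Named("converged") = conv);
}
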