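#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Sufficient statistics of the marginal Gaussian likelihood of a linear
// mixed model, accumulated per grouping unit (patient) via the Woodbury
// identity:
//   V_i^{-1} = R_i^{-1} - R_i^{-1} Z_i A_i^{-1} Z_i' R_i^{-1},
//   A_i      = D^{-1} + Z_i' R_i^{-1} Z_i,
//   log|V_i| = log|R_i| + log|D| + log|A_i|,
// with R_i diagonal (per-observation residual variances) and D the
// random-effects covariance, shared across patients.  Only q x q systems
// are factorized, never the n_i x n_i marginal covariance.
//
// y    : stacked response (N)
// X    : fixed-effects design (N x p)
// Z    : random-effects design (N x q)
// ptr  : 0-based row offsets per patient, length n_pat + 1
// rvar : per-observation residual variance (N)
// D    : q x q positive-definite random-effects covariance
//
// Returns logdet = sum_i log|V_i|, XtViX = X'V^{-1}X, XtViy = X'V^{-1}y,
// ytViy = y'V^{-1}y and ok = false when D (or any A_i) is not positive
// definite at the requested parameters.
// [[Rcpp::export(name = ".lmmSuffStats")]]
Rcpp::List lmm_suff_stats(const arma::vec& y, const arma::mat& X,
                          const arma::mat& Z, const arma::ivec& ptr,
                          const arma::vec& rvar, const arma::mat& D) {
  const arma::uword p = X.n_cols, q = Z.n_cols;
  const arma::uword npat = ptr.n_elem - 1;

  arma::mat failXtViX(p, p, arma::fill::zeros);
  Rcpp::List fail = Rcpp::List::create(
      Rcpp::Named("ok") = false, Rcpp::Named("logdet") = NA_REAL,
      Rcpp::Named("XtViX") = failXtViX,
      Rcpp::Named("XtViy") = arma::vec(p, arma::fill::zeros),
      Rcpp::Named("ytViy") = NA_REAL);

  arma::mat Ld;
  if (!arma::chol(Ld, D, "lower")) return fail;
  const double logdetD = 2.0 * arma::accu(arma::log(Ld.diag()));
  arma::mat Dinv;
  if (!arma::inv_sympd(Dinv, D)) return fail;

  double logdet = 0.0, ytViy = 0.0;
  arma::mat XtViX(p, p, arma::fill::zeros);
  arma::vec XtViy(p, arma::fill::zeros);

  for (arma::uword i = 0; i < npat; ++i) {
    const arma::uword a = (arma::uword)ptr(i), b = (arma::uword)ptr(i + 1) - 1;
    const arma::mat Zi = Z.rows(a, b);
    const arma::mat Xi = X.rows(a, b);
    const arma::vec yi = y.subvec(a, b);
    const arma::vec ri = rvar.subvec(a, b);
    const arma::vec rinv = 1.0 / ri;

    // U = [X_i | y_i]; S = U' V_i^{-1} U accumulated in one sweep
    arma::mat U(yi.n_elem, p + 1);
    U.head_cols(p) = Xi;
    U.col(p) = yi;
    arma::mat RU = U.each_col() % rinv;           // R^{-1} U
    arma::mat ZtRU = Zi.t() * RU;                 // q x (p+1)
    arma::mat A = Dinv + Zi.t() * (Zi.each_col() % rinv);
    arma::mat La;
    if (!arma::chol(La, A, "lower")) return fail;
    arma::mat W = arma::solve(arma::trimatl(La), ZtRU);
    arma::mat S = U.t() * RU - W.t() * W;

    logdet += arma::accu(arma::log(ri)) + logdetD +
              2.0 * arma::accu(arma::log(La.diag()));
    XtViX += S.submat(0, 0, p - 1, p - 1);
    XtViy += S.submat(0, p, p - 1, p);
    ytViy += S(p, p);
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("logdet") = logdet,
      Rcpp::Named("XtViX") = XtViX, Rcpp::Named("XtViy") = XtViy,
      Rcpp::Named("ytViy") = ytViy);
}
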