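// Restricted log-likelihood for a Gaussian mixed model with an arbitrary
// number of dense covariance structures plus an iid residual:
//
//   y ~ N(X beta,  V),   V = sum_k s2_k K_k + s2_e I
//
// The evaluator works block-wise: the caller partitions individuals into
// groups that are mutually independent under every K_k (connected components
// of the relatedness graph), so V is block diagonal and each Cholesky is
// small.  This is exact, not an approximation.
//
// REML criterion (Patterson-Thompson):
//   lR = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + r' V^-1 r ]
// with r = y - X betahat evaluated at the GLS solution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Accumulate the sufficient pieces over blocks.  `blocks` is a list of lists
// with elements y (numeric), X (matrix), K (list of matrices).
static bool accumulate(const List& blocks, const arma::vec& s2,
                       double s2e, int p, int m,
                       double& logdetV, arma::mat& XtViX,
                       arma::vec& XtViy, double& ytViy) {
  int nb = blocks.size();
  for (int b = 0; b < nb; ++b) {
    List blk = blocks[b];
    arma::vec y = as<arma::vec>(blk["y"]);
    arma::mat X = as<arma::mat>(blk["X"]);
    List Ks = blk["K"];
    int nbk = y.n_elem;
    arma::mat V(nbk, nbk, arma::fill::zeros);
    for (int k = 0; k < m; ++k) {
      if (s2[k] > 0.0) V += s2[k] * as<arma::mat>(Ks[k]);
    }
    V.diag() += s2e;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) return false;
    logdetV += 2.0 * arma::sum(arma::log(L.diag()));
    arma::vec Ly = arma::solve(arma::trimatl(L), y);
    arma::mat LX = arma::solve(arma::trimatl(L), X);
    XtViX += LX.t() * LX;
    XtViy += LX.t() * Ly;
    ytViy += arma::dot(Ly, Ly);
    (void)p;
  }
  return true;
}

// [[Rcpp::export(name = ".vc_nll")]]
double vc_nll(const arma::vec& log_s2, const List& blocks, int n, int p) {
  int m = log_s2.n_elem - 1;  // structures; last entry is residual
  arma::vec s2 = arma::exp(log_s2.head(m));
  double s2e = std::exp(log_s2[m]);
  double logdetV = 0.0, ytViy = 0.0;
  arma::mat XtViX(p, p, arma::fill::zeros);
  arma::vec XtViy(p, arma::fill::zeros);
  if (!accumulate(blocks, s2, s2e, p, m, logdetV, XtViX, XtViy, ytViy))
    return 1e10;
  double ld2, sign;
  if (!arma::log_det(ld2, sign, XtViX) || sign <= 0) return 1e10;
  arma::vec beta = arma::solve(XtViX, XtViy, arma::solve_opts::likely_sympd);
  double quad = ytViy - arma::dot(beta, XtViy);
  double lR = -0.5 * ((n - p) * std::log(2.0 * M_PI) + logdetV + ld2 + quad);
  return -lR;
}

// Same evaluation, returning the GLS coefficients and pieces for the caller.
// [[Rcpp::export(name = ".vc_fit_info")]]
List vc_fit_info(const arma::vec& log_s2, const List& blocks, int n, int p) {
  int m = log_s2.n_elem - 1;
  arma::vec s2 = arma::exp(log_s2.head(m));
  double s2e = std::exp(log_s2[m]);
  double logdetV = 0.0, ytViy = 0.0;
  arma::mat XtViX(p, p, arma::fill::zeros);
  arma::vec XtViy(p, arma::fill::zeros);
  bool ok = accumulate(blocks, s2, s2e, p, m, logdetV, XtViX, XtViy, ytViy);
  if (!ok) stop("covariance matrix not positive definite");
  double ld2, sign;
  arma::log_det(ld2, sign, XtViX);
  arma::vec beta = arma::solve(XtViX, XtViy, arma::solve_opts::likely_sympd);
  double quad = ytViy - arma::dot(beta, XtViy);
  double lR = -0.5 * ((n - p) * std::log(2.0 * M_PI) + logdetV + ld2 + quad);
  return List::create(_["beta"] = beta,
                      _["vcov"] = arma::inv_sympd(arma::symmatu(XtViX)),
                      _["loglik"] = lR);
}
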