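#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Profile likelihood machinery for the Gaussian variance-component model
//   V = sigma2 * (I + gamma_1 K1 [+ gamma_2 K2])
// over independent family blocks. Fixed effects (GLS) and sigma2 are
// profiled analytically; the gradient is with respect to gamma (envelope
// theorem). The per-scan data (y, X, 2Phi blocks) are held in an external
// pointer so that repeated evaluations and position-wise kernel swaps avoid
// any re-copying from R.

struct VcModel {
  std::vector<arma::vec> y;
  std::vector<arma::mat> X;
  std::vector<arma::mat> K1;
  std::vector<arma::mat> K2;
  int n = 0, p = 0;
};

// [[Rcpp::export]]
SEXP vcBuild(List yl, List Xl, List K1l) {
  XPtr<VcModel> m(new VcModel, true);
  int F = yl.size();
  m->y.resize(F); m->X.resize(F); m->K1.resize(F);
  for (int f = 0; f < F; ++f) {
    m->y[f] = as<arma::vec>(yl[f]);
    m->X[f] = as<arma::mat>(Xl[f]);
    m->K1[f] = as<arma::mat>(K1l[f]);
    m->n += m->y[f].n_elem;
  }
  m->p = m->X[0].n_cols;
  return m;
}

// [[Rcpp::export]]
void vcSetK2(SEXP ptr, List K2l) {
  XPtr<VcModel> m(ptr);
  int F = K2l.size();
  m->K2.resize(F);
  for (int f = 0; f < F; ++f) m->K2[f] = as<arma::mat>(K2l[f]);
}

// full = FALSE: just nll and gradient (for the optimizer);
// full = TRUE: adds beta, sigma2, per-family log-likelihoods and X'V~X.
// [[Rcpp::export]]
List vcEval(SEXP ptr, arma::vec gamma, int nK, bool full) {
  XPtr<VcModel> m(ptr);
  const int F = m->y.size();
  const double g1 = gamma(0);
  const double g2 = nK > 1 ? gamma(1) : 0.0;
  if (nK > 1 && (int)m->K2.size() != F) stop("K2 blocks not set");

  std::vector<arma::mat> Vi(F);
  arma::vec logdet(F, arma::fill::zeros);
  arma::mat XtVX(m->p, m->p, arma::fill::zeros);
  arma::vec XtVy(m->p, arma::fill::zeros);
  double ytVy = 0.0;

  for (int f = 0; f < F; ++f) {
    arma::mat V = g1 * m->K1[f];
    if (nK > 1) V += g2 * m->K2[f];
    V.diag() += 1.0;
    arma::mat Vinv;
    if (!arma::inv_sympd(Vinv, V)) {
      V.diag() += 1e-10;
      if (!arma::inv_sympd(Vinv, V)) stop("covariance not invertible");
    }
    double ld, sign;
    arma::log_det(ld, sign, V);
    logdet(f) = ld;
    arma::mat ViX = Vinv * m->X[f];
    XtVX += m->X[f].t() * ViX;
    XtVy += ViX.t() * m->y[f];
    ytVy += arma::dot(m->y[f], Vinv * m->y[f]);
    Vi[f] = std::move(Vinv);
  }

  arma::vec beta = arma::solve(XtVX, XtVy, arma::solve_opts::likely_sympd);
  double rss = ytVy - arma::dot(beta, XtVy);
  if (rss < 1e-300) rss = 1e-300;
  const int n = m->n;
  double sigma2 = rss / n;
  const double l2pi = std::log(2.0 * M_PI);
  double nll = 0.5 * (n * (l2pi + std::log(sigma2)) + n + arma::accu(logdet));

  arma::vec grad(nK, arma::fill::zeros);
  arma::vec llFam(F);
  for (int f = 0; f < F; ++f) {
    arma::vec r = m->y[f] - m->X[f] * beta;
    arma::vec rt = Vi[f] * r;
    grad(0) += 0.5 * arma::accu(Vi[f] % m->K1[f]) -
      0.5 * n * arma::as_scalar(rt.t() * m->K1[f] * rt) / rss;
    if (nK > 1)
      grad(1) += 0.5 * arma::accu(Vi[f] % m->K2[f]) -
        0.5 * n * arma::as_scalar(rt.t() * m->K2[f] * rt) / rss;
    if (full)
      llFam(f) = -0.5 * (m->y[f].n_elem * (l2pi + std::log(sigma2)) +
                         logdet(f) + arma::dot(r, rt) / sigma2);
  }

  if (!full)
    return List::create(_["nll"] = nll, _["grad"] = grad);
  return List::create(_["nll"] = nll, _["grad"] = grad, _["beta"] = beta,
                      _["sigma2"] = sigma2, _["llFam"] = llFam,
                      _["ll"] = -nll, _["XtVX"] = XtVX);
}
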