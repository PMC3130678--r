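// Fast negative log-likelihood of the multi-peak multivariate OU
// (Hansen) model, with the optima concentrated out by GLS.  Mirrors the
// reference implementation in R/hansen.R (hansen_eval); the two are
// cross-checked in the test suite.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// rebuild A (log-Cholesky) and S (lower triangular, log diagonal)
static void par_to_AS(const arma::vec& par, int p, arma::mat& A,
                      arma::mat& S) {
  int nL = p * (p + 1) / 2;
  arma::mat L(p, p, arma::fill::zeros), Ls(p, p, arma::fill::zeros);
  int ia = 0, is = nL;
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i) L(i, j) = par[ia++];
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i) Ls(i, j) = par[is++];
  for (int i = 0; i < p; ++i) {
    L(i, i) = std::exp(L(i, i));
    Ls(i, i) = std::exp(Ls(i, i));
  }
  A = L * L.t();
  S = Ls;
}

// [[Rcpp::export]]
double hansen_nll_cpp(const arma::vec& par, const List& pre) {
  const arma::mat& X = as<arma::mat>(pre["X"]);
  const arma::mat& Smat = as<arma::mat>(pre["Smat"]);
  const arma::mat& Dif = as<arma::mat>(pre["Dif"]);   // TiM - Smat
  const arma::vec& depth = as<arma::vec>(pre["depth"]);
  const arma::ivec& seg_tip = as<arma::ivec>(pre["seg_tip"]);
  const arma::vec& seg_ta = as<arma::vec>(pre["seg_ta"]);
  const arma::vec& seg_tb = as<arma::vec>(pre["seg_tb"]);
  const arma::ivec& seg_regime = as<arma::ivec>(pre["seg_regime"]);
  const int nr = as<int>(pre["nr"]);
  const int root_regime = as<int>(pre["root_regime"]) - 1;
  const int n = X.n_rows, p = X.n_cols;
  const double big = 1e10;

  arma::mat A, S;
  par_to_AS(par, p, A, S);
  arma::vec lam;
  arma::mat U;
  if (!arma::eig_sym(lam, U, A)) return big;
  if (lam.min() <= 0 || !lam.is_finite()) return big;
  arma::mat Sigma = S * S.t();
  arma::mat D = U.t() * Sigma * U;

  // block (k,l): D_kl exp(-l_k (T_i - s)) exp(-l_l (T_j - s))
  //              (1 - exp(-(l_k+l_l) s)) / (l_k + l_l)
  // fast path: the two depth factors are rank-1, leaving one
  // elementwise expm1; falls back to the overflow-safe three-exp form
  // when (l_k + l_l) * max(s) would overflow exp
  const double smax = Smat.max();
  arma::vec ek(n), el(n);
  arma::mat V(n * p, n * p, arma::fill::zeros);
  for (int k = 0; k < p; ++k) {
    for (int l = k; l < p; ++l) {
      double ls = lam[k] + lam[l];
      arma::mat M;
      if (ls < 1e-12) {
        M = D(k, l) * Smat;
      } else if (ls * smax < 600.0) {
        ek = arma::exp(-lam[k] * depth);
        el = arma::exp(-lam[l] * depth);
        M = D(k, l) * ((ek * el.t()) % (arma::expm1(ls * Smat) / ls));
      } else {
        M = D(k, l) * (arma::exp(-lam[k] * Dif) %
                       arma::exp(-lam[l] * Dif).t() %
                       ((1.0 - arma::exp(-ls * Smat)) / ls));
      }
      V.submat(k * n, l * n, (k + 1) * n - 1, (l + 1) * n - 1) = M;
    }
  }

  arma::mat R;
  if (!arma::chol(R, V, "upper")) return big;

  // block-diagonal regime-weight design in the eigenbasis
  arma::mat W(n * p, nr * p, arma::fill::zeros);
  int nseg = seg_tip.n_elem;
  for (int k = 0; k < p; ++k) {
    arma::mat Wk(n, nr, arma::fill::zeros);
    for (int s = 0; s < nseg; ++s) {
      int i = seg_tip[s] - 1, r = seg_regime[s] - 1;
      Wk(i, r) += std::exp(-lam[k] * (depth[i] - seg_tb[s])) -
                  std::exp(-lam[k] * (depth[i] - seg_ta[s]));
    }
    for (int i = 0; i < n; ++i)
      Wk(i, root_regime) += std::exp(-lam[k] * depth[i]);
    W.submat(k * n, k * nr, (k + 1) * n - 1, (k + 1) * nr - 1) = Wk;
  }

  if (!R.is_finite() || R.diag().min() <= 0) return big;
  arma::vec z = arma::vectorise(X * U);
  arma::mat Wt, G;
  arma::vec zt, th;
  if (!arma::solve(Wt, arma::trimatl(R.t()), W,
                   arma::solve_opts::no_approx)) return big;
  if (!arma::solve(zt, arma::trimatl(R.t()), z,
                   arma::solve_opts::no_approx)) return big;
  G = Wt.t() * Wt;
  if (!arma::solve(th, G, Wt.t() * zt, arma::solve_opts::no_approx))
    return big;
  arma::vec resid = zt - Wt * th;
  double quad = arma::dot(resid, resid);
  double logdet = 2.0 * arma::sum(arma::log(R.diag()));
  double nll = 0.5 * (n * p * std::log(2.0 * M_PI) + logdet + quad);
  if (!std::isfinite(nll)) return big;
  return nll;
}
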