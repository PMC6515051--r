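// Profile likelihood core for the pairwise GY94 estimator.  For fixed
// (kappa, omega) this builds the scaled reversible generator over the 61
// sense codons, diagonalizes its symmetrized form, and profiles the total
// divergence t out by a golden-section search on log t.  Keeping the whole
// evaluation compiled makes the outer (kappa, omega) optimization cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double nll_at(const arma::vec& lam, const arma::mat& Mobs,
                     const arma::vec& nobs, const arma::vec& lpi_obs,
                     double t) {
  arma::vec p = Mobs * arma::exp(lam * t);
  p.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
  return -arma::dot(nobs, lpi_obs + arma::log(p));
}

// [[Rcpp::export(name = ".gy94_profile_nll")]]
List gy94_profile_nll(double kappa, double omega, const arma::vec& pi,
                      const arma::uvec& si, const arma::uvec& sj,
                      const arma::uvec& is_ts, const arma::uvec& is_syn,
                      const arma::uvec& oi, const arma::uvec& oj,
                      const arma::vec& on, double t_lo, double t_hi) {
  const arma::uword n = 61;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword k = 0; k < si.n_elem; ++k) {
    double r = (is_ts[k] ? kappa : 1.0) * (is_syn[k] ? 1.0 : omega);
    Q(si[k], sj[k]) = r * pi[sj[k]];
  }
  arma::vec rs = arma::sum(Q, 1);
  double total = arma::dot(pi, rs);
  Q /= total;
  rs /= total;
  Q.diag() = -rs;

  arma::vec sp = arma::sqrt(pi);
  arma::mat B = Q;
  for (arma::uword r = 0; r < n; ++r)
    for (arma::uword c = 0; c < n; ++c)
      B(r, c) *= sp[r] / sp[c];
  B = 0.5 * (B + B.t());
  arma::vec lam;
  arma::mat V;
  if (!arma::eig_sym(lam, V, B))
    stop("eigendecomposition failed");

  arma::mat A = V;
  A.each_col() /= sp;                       // A_ik = V_ik / sqrt(pi_i)
  arma::mat Ainv = V.t();
  Ainv.each_row() %= sp.t();                // (V' D)_kj = V_jk sqrt(pi_j)

  const arma::uword m = oi.n_elem;
  arma::mat Mobs(m, n);
  arma::vec lpi_obs(m);
  for (arma::uword r = 0; r < m; ++r) {
    Mobs.row(r) = A.row(oi[r]) % Ainv.col(oj[r]).t();
    lpi_obs[r] = std::log(pi[oi[r]]);
  }

  // golden-section minimization over log t
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = std::log(t_lo), b = std::log(t_hi);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = nll_at(lam, Mobs, on, lpi_obs, std::exp(x1));
  double f2 = nll_at(lam, Mobs, on, lpi_obs, std::exp(x2));
  for (int it = 0; it < 70; ++it) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = nll_at(lam, Mobs, on, lpi_obs, std::exp(x1));
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = nll_at(lam, Mobs, on, lpi_obs, std::exp(x2));
    }
    if (b - a < 1e-8) break;
  }
  double lt = (f1 <= f2) ? x1 : x2;
  double fbest = std::min(f1, f2);
  // the optimum may hug an interval end (e.g. identical sequences)
  double f_lo = nll_at(lam, Mobs, on, lpi_obs, t_lo);
  double f_hi = nll_at(lam, Mobs, on, lpi_obs, t_hi);
  if (f_lo < fbest) { fbest = f_lo; lt = std::log(t_lo); }
  if (f_hi < fbest) { fbest = f_hi; lt = std::log(t_hi); }

  return List::create(_["nll"] = fbest, _["t"] = std::exp(lt));
}
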