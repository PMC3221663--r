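// Felsenstein pruning for the 61-state codon model with site-class mixtures.
// One call evaluates, for every alignment pattern and every site class, the
// log-likelihood log P(pattern | class) on a fixed tree. Class rate matrices
// share kappa and the equilibrium frequencies and differ in omega; all
// classes are scaled by the common expected substitution rate so branch
// lengths are expected substitutions per codon averaged over classes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat build_Q(const arma::vec& pi, double kappa, double omega,
                         const IntegerVector& pi_idx, const IntegerVector& pj_idx,
                         const IntegerVector& is_ts, const IntegerVector& is_syn) {
  arma::mat Q(61, 61, arma::fill::zeros);
  int m = pi_idx.size();
  for (int r = 0; r < m; ++r) {
    double rate = (is_ts[r] ? kappa : 1.0) * (is_syn[r] ? 1.0 : omega);
    Q(pi_idx[r], pj_idx[r]) = rate * pi(pj_idx[r]);
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// [[Rcpp::export]]
arma::mat site_class_loglik_cpp(const IntegerMatrix& edge,       // nedge x 2, 1-based, postorder
                                const arma::vec& blens,          // per edge
                                int n_tip, int n_node,
                                const IntegerMatrix& tipstates,  // n_tip x npat, 1-based, 0 = gap
                                const arma::vec& pi,
                                double kappa,
                                const arma::vec& omegas,
                                const arma::vec& props,
                                const IntegerVector& pi_idx, const IntegerVector& pj_idx,
                                const IntegerVector& is_ts, const IntegerVector& is_syn) {
  const int K = omegas.n_elem;
  const int npat = tipstates.ncol();
  const int nedge = edge.nrow();
  const int ntot = n_tip + n_node;

  // class generators under the common scale
  std::vector<arma::mat> Qs(K);
  double mu = 0.0;
  for (int k = 0; k < K; ++k) {
    Qs[k] = build_Q(pi, kappa, omegas[k], pi_idx, pj_idx, is_ts, is_syn);
    mu += props[k] * arma::dot(pi, -Qs[k].diag());
  }
  if (mu <= 0) stop("degenerate rate matrix scale");

  arma::vec sq = arma::sqrt(pi);
  arma::mat Dinv = arma::diagmat(1.0 / sq), D = arma::diagmat(sq);

  arma::mat out(npat, K);
  for (int k = 0; k < K; ++k) {
    arma::mat B = D * (Qs[k] / mu) * Dinv;
    B = 0.5 * (B + B.t());
    arma::vec eval; arma::mat evec;
    if (!arma::eig_sym(eval, evec, B)) stop("eigendecomposition failed");
    arma::mat left = Dinv * evec;          // 61 x 61
    arma::mat right = evec.t() * D;        // 61 x 61

    // per-edge transition matrices
    std::vector<arma::mat> P(nedge);
    for (int e = 0; e < nedge; ++e) {
      arma::vec ex = arma::exp(eval * blens[e]);
      arma::mat Pe = left * arma::diagmat(ex) * right;
      Pe.clamp(0.0, arma::datum::inf);
      P[e] = Pe;
    }

    // partial likelihoods, postorder
    std::vector<arma::mat> part(ntot);
    std::vector<bool> init(ntot, false);
    arma::mat lsc(ntot, npat, arma::fill::zeros);
    for (int e = 0; e < nedge; ++e) {
      int parent = edge(e, 0) - 1, child = edge(e, 1) - 1;
      arma::mat msg(61, npat);
      if (child < n_tip) {
        const arma::mat& Pe = P[e];
        arma::vec ones61(61, arma::fill::ones);
        for (int s = 0; s < npat; ++s) {
          int st = tipstates(child, s);
          if (st == 0) msg.col(s) = ones61;
          else msg.col(s) = Pe.col(st - 1);
        }
      } else {
        msg = P[e] * part[child];
      }
      if (!init[parent]) { part[parent] = msg; init[parent] = true; }
      else part[parent] %= msg;
      if (child >= n_tip) lsc.row(parent) += lsc.row(child);
      // rescale columns that drift small
      arma::rowvec mx = arma::max(part[parent], 0);
      for (int s = 0; s < npat; ++s) {
        if (mx(s) > 0 && mx(s) < 1e-100) {
          part[parent].col(s) /= mx(s);
          lsc(parent, s) += std::log(mx(s));
        }
      }
    }
    int root = edge(nedge - 1, 0) - 1;  // postorder: last edge's parent
    arma::rowvec lik = pi.t() * part[root];
    for (int s = 0; s < npat; ++s)
      out(s, k) = (lik(s) > 0 ? std::log(lik(s)) : -arma::datum::inf) + lsc(root, s);
  }
  return out;
}
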