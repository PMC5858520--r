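// Post-order pruning likelihood kernel. The tree arrives as a postorder
// edge list; tip partial-likelihood matrices (4 x patterns) come in tree
// tip order and are used as views without copying; P(t) per edge is
// rebuilt from the model's symmetric eigendecomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double loglik_pruned_cpp(const arma::imat& edge, const arma::vec& len,
                         const Rcpp::List& tipL, int ntip, int nnode,
                         const arma::mat& right, const arma::vec& eval,
                         const arma::mat& left, const arma::vec& pi,
                         const arma::vec& w) {
  const int ntot = ntip + nnode;
  const int nedge = edge.n_rows;
  const int npat = w.n_elem;
  std::vector<mat> L(ntot);
  std::vector<bool> has(ntot, false);
  for (int i = 0; i < ntip; ++i) {
    Rcpp::NumericMatrix tm = tipL[i];
    L[i] = mat(tm.begin(), tm.nrow(), tm.ncol(), false, true);
    has[i] = true;
  }
  mat P(4, 4);
  for (int k = 0; k < nedge; ++k) {
    const int p = edge(k, 0) - 1;
    const int c = edge(k, 1) - 1;
    P = right * diagmat(exp(eval * len[k])) * left;
    P.elem(find(P < 0)).zeros();
    if (!has[p]) {
      L[p] = P * L[c];
      has[p] = true;
    } else {
      L[p] %= P * L[c];
    }
  }
  const int root = edge(nedge - 1, 0) - 1;
  rowvec site = pi.t() * L[root];
  double total = 0.0;
  for (int j = 0; j < npat; ++j) total += w[j] * std::log(site[j]);
  return total;
}
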