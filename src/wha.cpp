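// Searchlight warp-hyperalignment inner loop.
//
// For every bagging model we form the bootstrapped Gram matrix of the
// template once over all vertices, then solve the local ridge systems per
// searchlight on index subsets.  All participants share the fold plan and
// the template, so their systems share the factorization of the local
// Gram matrix and are solved together as a wide right-hand side.  This
// keeps the per-model work dominated by level-3 BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_fit_wha_multi(const arma::mat& M, const List& B_list,
                       const List& boot_idx, const List& members,
                       const List& weights, double lambda) {
  const arma::uword v = M.n_cols;
  const int nmod = boot_idx.size();
  const int nsl = members.size();
  const int nsub = B_list.size();

  std::vector<arma::uvec> mem(nsl);
  std::vector<arma::vec> wts(nsl);
  for (int s = 0; s < nsl; s++) {
    mem[s] = as<arma::uvec>(members[s]) - 1;
    wts[s] = as<arma::vec>(weights[s]);
  }
  std::vector<arma::mat> B(nsub);
  for (int p = 0; p < nsub; p++) B[p] = as<arma::mat>(B_list[p]);
  std::vector<arma::mat> num(nsub, arma::mat(v, v, arma::fill::zeros));
  arma::vec den(v, arma::fill::zeros);

  for (int m = 0; m < nmod; m++) {
    arma::uvec idx = as<arma::uvec>(boot_idx[m]) - 1;
    arma::mat Mb = M.rows(idx);
    arma::mat G = Mb.t() * Mb;
    // cross-products with every participant's bootstrapped rows,
    // concatenated column-wise: C = Mb' [B1b | B2b | ...]
    arma::mat C(v, v * nsub);
    for (int p = 0; p < nsub; p++)
      C.cols(p * v, (p + 1) * v - 1) = Mb.t() * B[p].rows(idx);
    for (int s = 0; s < nsl; s++) {
      const arma::uvec& u = mem[s];
      const arma::uword q = u.n_elem;
      arma::mat Gs = G.submat(u, u);
      Gs.diag() += lambda;
      arma::uvec ucols(q * nsub);
      for (int p = 0; p < nsub; p++)
        ucols.subvec(p * q, (p + 1) * q - 1) = u + p * v;
      // explicit inverse + GEMM beats triangular solves for the wide
      // multi-participant right-hand side; Gs is well conditioned
      // (lambda added to the diagonal)
      arma::mat Ws = arma::inv_sympd(Gs) * C.submat(u, ucols);
      for (int p = 0; p < nsub; p++) {
        arma::mat Wp = Ws.cols(p * q, (p + 1) * q - 1);
        Wp.each_row() %= wts[s].t();  // weight columns by target vertex
        num[p].submat(u, u) += Wp;
      }
      den.elem(u) += wts[s];
    }
  }
  List out(nsub);
  for (int p = 0; p < nsub; p++) {
    num[p].each_row() /= den.t();
    out[p] = num[p];
  }
  return out;
}
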