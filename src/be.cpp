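// Permutation null spectra for the parallel-analysis latent-factor count.
#include <RcppArmadillo.h>
using namespace Rcpp;

// resid: G x N residual matrix (already orthogonal to the design).
// imh:   N x N annihilator I - H of the design.
// B:     number of permutations; ndf: number of leading components compared.
// For each permutation every row of resid is shuffled independently
// (Fisher-Yates on R's RNG, so set.seed() governs), the design is projected
// back out, and the eigenvalue proportions of the permuted cross-product
// are compared component-wise against the observed ones. The projection is
// applied to the N x N cross-product — (I-H) R'R (I-H) has the same
// spectrum as crossprod(Rperm %*% (I-H)) — so each permutation costs one
// G*N^2 GEMM instead of two.
// [[Rcpp::export]]
List be_exceed_counts(const arma::mat& resid, const arma::mat& imh,
                      int B, int ndf) {
  const arma::uword G = resid.n_rows, N = resid.n_cols;
  if (ndf < 1 || (arma::uword)ndf > N) stop("invalid ndf");

  arma::mat C = imh * (resid.t() * resid) * imh;
  arma::vec ev = arma::reverse(arma::eig_sym(C));
  arma::vec obs = ev.head(ndf);
  obs.elem(arma::find(obs < 0)).zeros();
  double tot = arma::accu(obs);
  if (tot <= 0) {
    // degenerate (zero residual): report everything as non-significant
    return List::create(_["obs"] = NumericVector(ndf),
                        _["exceed"] = NumericVector(ndf, (double)B));
  }
  obs /= tot;

  arma::vec exceed(ndf, arma::fill::zeros);
  arma::mat Rp = resid;
  GetRNGstate();
  for (int b = 0; b < B; ++b) {
    for (arma::uword g = 0; g < G; ++g) {
      for (arma::uword j = N - 1; j > 0; --j) {
        arma::uword k = (arma::uword)(unif_rand() * (j + 1));
        if (k > j) k = j;
        double tmp = Rp(g, j); Rp(g, j) = Rp(g, k); Rp(g, k) = tmp;
      }
    }
    arma::mat Cp = imh * (Rp.t() * Rp) * imh;
    arma::vec evp = arma::reverse(arma::eig_sym(Cp));
    arma::vec prop = evp.head(ndf);
    prop.elem(arma::find(prop < 0)).zeros();
    prop /= arma::accu(prop);
    exceed += arma::conv_to<arma::vec>::from(prop >= obs);
  }
  PutRNGstate();
  return List::create(_["obs"] = obs, _["exceed"] = exceed);
}
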