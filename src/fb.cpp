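// Scaled forward-backward posterior decoding for a time-inhomogeneous HMM.
// The transition matrix at each step is picked from a small set of templates
// by an integer code (the phased model selects among four matrices according
// to the heterozygosity pattern of the next observation; the genotype model
// uses a single template throughout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// init: K initial distribution; emis: T x K emission probabilities;
// trans: list of K x K row-stochastic templates; code: (T-1) 1-based
// template index for the transition into each locus t = 2..T.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(arma::vec init, arma::mat emis, List trans, arma::ivec code) {
  const int T = emis.n_rows, K = emis.n_cols;
  if ((int)init.n_elem != K) stop("init/emission dimension mismatch");
  if (T > 1 && (int)code.n_elem != T - 1) stop("need T-1 transition codes");

  std::vector<arma::mat> A(trans.size());
  for (int m = 0; m < trans.size(); ++m) {
    A[m] = as<arma::mat>(trans[m]);
    if ((int)A[m].n_rows != K || (int)A[m].n_cols != K)
      stop("transition template dimension mismatch");
  }

  arma::mat alpha(T, K), beta(T, K);
  arma::vec c(T);

  arma::vec a = init % emis.row(0).t();
  c(0) = arma::accu(a);
  if (c(0) <= 0) stop("total likelihood underflow at locus 1");
  alpha.row(0) = (a / c(0)).t();

  for (int t = 1; t < T; ++t) {
    const arma::mat &M = A[code(t - 1) - 1];
    a = (M.t() * alpha.row(t - 1).t()) % emis.row(t).t();
    c(t) = arma::accu(a);
    if (c(t) <= 0) stop("total likelihood underflow at locus " +
                        std::to_string(t + 1));
    alpha.row(t) = (a / c(t)).t();
  }

  beta.row(T - 1).ones();
  for (int t = T - 2; t >= 0; --t) {
    const arma::mat &M = A[code(t) - 1];
    arma::vec b = M * (emis.row(t + 1).t() % beta.row(t + 1).t());
    beta.row(t) = (b / c(t + 1)).t();
  }

  arma::mat post = alpha % beta;
  post.each_col() /= arma::sum(post, 1); // guard against rounding drift
  return List::create(_["posterior"] = post,
                      _["loglik"] = arma::accu(arma::log(c)));
}
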