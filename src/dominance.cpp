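// All-subset R^2 enumeration for dominance analysis.
//
// Inputs are the predictor correlation matrix and the predictor-outcome
// correlation vector of standardized data, from which the R^2 of every one
// of the 2^p - 1 submodels is C_yS' C_SS^{-1} C_yS. Total dominance of
// predictor k is the average over subset sizes of the mean increase in R^2
// when k joins a submodel; the totals sum exactly to the full-model R^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int popcount(unsigned long x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountl(x);
#else
  int c = 0;
  while (x) { c += x & 1UL; x >>= 1; }
  return c;
#endif
}

// [[Rcpp::export(name = ".dominanceCore")]]
List dominanceCore(const arma::mat& R, const arma::vec& ry) {
  const int p = R.n_rows;
  if (p < 1 || p > 25) stop("predictor count out of range");
  const unsigned long nmask = 1UL << p;

  std::vector<double> r2(nmask, 0.0);
  arma::uvec idx(p);
  for (unsigned long mask = 1; mask < nmask; ++mask) {
    int k = 0;
    for (int j = 0; j < p; ++j) {
      if (mask & (1UL << j)) idx(k++) = j;
    }
    arma::uvec ii = idx.head(k);
    arma::mat C = R.submat(ii, ii);
    arma::vec c = ry.elem(ii);
    arma::vec beta;
    bool ok = arma::solve(beta, C, c,
                          arma::solve_opts::likely_sympd +
                          arma::solve_opts::no_approx);
    if (!ok) beta = arma::pinv(C) * c;  // duplicated/collinear predictors
    r2[mask] = arma::dot(c, beta);
  }

  // sums(k, s): summed increments over submodels of size s lacking k.
  arma::mat sums(p, p, arma::fill::zeros);
  for (unsigned long mask = 0; mask < nmask; ++mask) {
    const int s = popcount(mask);
    for (int k = 0; k < p; ++k) {
      if (!(mask & (1UL << k))) {
        sums(k, s) += r2[mask | (1UL << k)] - r2[mask];
      }
    }
  }

  arma::vec total(p, arma::fill::zeros);
  for (int k = 0; k < p; ++k) {
    double acc = 0.0;
    for (int s = 0; s < p; ++s) {
      const double nsub = std::exp(R::lchoose(p - 1, s));
      acc += sums(k, s) / nsub;
    }
    total(k) = acc / p;
  }

  return List::create(_["total"] = NumericVector(total.begin(), total.end()),
                      _["r2full"] = r2[nmask - 1]);
}
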