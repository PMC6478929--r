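#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a K-state HMM.
//
// emis:  T x K matrix of per-frame emission likelihoods (strictly positive)
// trans: K x K row-stochastic transition matrix
// init:  length-K initial distribution
//
// Returns per-frame posteriors gamma (T x K), summed pairwise expected
// transition counts xi_sum (K x K) and the total log-likelihood. Scaling by
// the per-frame normalizer keeps the recursion in range for arbitrarily long
// tracks (contract: no underflow at 1e5+ frames).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix emis, NumericMatrix trans,
                          NumericVector init) {
  const int T = emis.nrow();
  const int K = emis.ncol();
  if (trans.nrow() != K || trans.ncol() != K || init.size() != K)
    stop("dimension mismatch between emissions, transitions and init");

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T);
  NumericMatrix xi_sum(K, K);

  // forward pass
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * emis(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0) stop("zero total emission probability at frame 1");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= emis(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("zero total emission probability at frame " +
                       std::to_string(t + 1));
    scale[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  // backward pass
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(i, j) * emis(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / scale[t + 1];
    }
  }

  // posteriors and pairwise expected transitions
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      if (alpha(t, i) == 0.0) continue;
      for (int j = 0; j < K; ++j) {
        if (trans(i, j) == 0.0) continue;
        xi_sum(i, j) += alpha(t, i) * trans(i, j) * emis(t + 1, j) *
                        beta(t + 1, j) / scale[t + 1];
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = ll);
}
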