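#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for one observation sequence.
//
// B  : T x K matrix of per-bin emission likelihoods P(x_t | state k)
// A  : K x K row-stochastic transition matrix
// pi : initial state distribution
// X  : T x F binary observation matrix (needed to accumulate the
//      emission sufficient statistics sum_t gamma[t,k] * x[t,f])
//
// Returns the expected sufficient statistics for Baum-Welch plus the
// scaled log-likelihood. When return_gamma is true the full T x K
// posterior matrix is included (used for posterior decoding).
// [[Rcpp::export(name = ".hmm_estep")]]
List hmm_estep(NumericMatrix B, NumericMatrix A, NumericVector pi,
               NumericMatrix X, bool return_gamma = false) {
  const int T = B.nrow(), K = B.ncol(), F = X.ncol();
  if (X.nrow() != T) stop("X and B must have the same number of rows");

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector cvec(T);

  // forward pass with per-bin scaling
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi[k] * B(0, k);
    c0 += alpha(0, k);
  }
  if (c0 <= 0.0) stop("zero forward probability at bin 1");
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  cvec[0] = c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
      double v = s * B(t, k);
      alpha(t, k) = v;
      ct += v;
    }
    if (ct <= 0.0) stop("zero forward probability at bin %d", t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    cvec[t] = ct;
  }

  // backward pass, scaled by the same constants
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = s / cvec[t + 1];
    }
  }

  // posterior gamma and accumulated statistics
  NumericVector gamma_sum(K), gamma_first(K);
  NumericMatrix gamma_x(K, F), xi_sum(K, K);
  NumericMatrix gamma_full(return_gamma ? T : 1, return_gamma ? K : 1);

  std::vector<double> g(K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      g[k] = alpha(t, k) * beta(t, k);
      norm += g[k];
    }
    for (int k = 0; k < K; ++k) {
      g[k] /= norm;
      gamma_sum[k] += g[k];
      for (int f = 0; f < F; ++f)
        if (X(t, f) != 0.0) gamma_x(k, f) += g[k];
      if (return_gamma) gamma_full(t, k) = g[k];
    }
    if (t == 0)
      for (int k = 0; k < K; ++k) gamma_first[k] = g[k];
  }

  // xi: expected transition counts
  for (int t = 0; t < T - 1; ++t) {
    double norm = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        norm += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    if (norm <= 0.0) continue;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / norm;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]);

  List out = List::create(
    _["loglik"] = loglik,
    _["gamma_sum"] = gamma_sum,
    _["gamma_x"] = gamma_x,
    _["xi_sum"] = xi_sum,
    _["gamma_first"] = gamma_first);
  if (return_gamma) out["gamma"] = gamma_full;
  return out;
}
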