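// Forward-backward and Viterbi for a shared Gaussian-emission HMM over
// many independent observation sequences (concatenated, with lengths).
// Scaled-probability recursions for numerical safety.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dnorm_pdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// E-step over all sequences.
// x: concatenated observations; len: per-sequence lengths;
// mu, sigma: K emission parameters; A: K x K transition matrix;
// pi0: initial distribution.
// Returns total log-likelihood, per-frame posteriors (gamma),
// summed transition expectations (xi), and summed t=1 posteriors.
// [[Rcpp::export(name = ".hmmEStep")]]
List hmmEStep(NumericVector x, IntegerVector len, NumericVector mu,
              NumericVector sigma, NumericMatrix A, NumericVector pi0) {
  const int K = mu.size();
  const int N = x.size();
  NumericMatrix gamma(N, K);
  NumericMatrix xiSum(K, K);
  NumericVector initSum(K);
  double loglik = 0.0;

  std::vector<double> alpha(static_cast<size_t>(N) * K);
  std::vector<double> beta(static_cast<size_t>(N) * K);
  std::vector<double> b(static_cast<size_t>(N) * K);
  std::vector<double> scale(N);

  int offset = 0;
  for (int s = 0; s < len.size(); ++s) {
    const int T = len[s];
    // emission densities (floored to avoid zero rows)
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) {
        double d = dnorm_pdf(x[offset + t], mu[k], sigma[k]);
        b[(offset + t) * K + k] = (d < 1e-300) ? 1e-300 : d;
      }
    // forward with scaling
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = pi0[k] * b[offset * K + k];
      alpha[offset * K + k] = v;
      c0 += v;
    }
    scale[offset] = c0;
    for (int k = 0; k < K; ++k) alpha[offset * K + k] /= c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += alpha[(offset + t - 1) * K + j] * A(j, k);
        double v = acc * b[(offset + t) * K + k];
        alpha[(offset + t) * K + k] = v;
        ct += v;
      }
      scale[offset + t] = ct;
      for (int k = 0; k < K; ++k) alpha[(offset + t) * K + k] /= ct;
    }
    // backward with the same scaling
    for (int k = 0; k < K; ++k) beta[(offset + T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j)
          acc += A(k, j) * b[(offset + t + 1) * K + j] *
                 beta[(offset + t + 1) * K + j];
        beta[(offset + t) * K + k] = acc / scale[offset + t + 1];
      }
    }
    // posteriors and transition expectations
    for (int t = 0; t < T; ++t) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k)
        norm += alpha[(offset + t) * K + k] * beta[(offset + t) * K + k];
      for (int k = 0; k < K; ++k)
        gamma(offset + t, k) =
            alpha[(offset + t) * K + k] * beta[(offset + t) * K + k] /
            norm;
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < K; ++j)
          xiSum(k, j) += alpha[(offset + t) * K + k] * A(k, j) *
                         b[(offset + t + 1) * K + j] *
                         beta[(offset + t + 1) * K + j] /
                         scale[offset + t + 1];
    }
    for (int k = 0; k < K; ++k) initSum[k] += gamma(offset, k);
    for (int t = 0; t < T; ++t) loglik += std::log(scale[offset + t]);
    offset += T;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xiSum"] = xiSum, _["initSum"] = initSum);
}

// Viterbi most-probable path for one sequence (log space).
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmmViterbi")]]
IntegerVector hmmViterbi(NumericVector x, NumericVector mu,
                         NumericVector sigma, NumericMatrix A,
                         NumericVector pi0) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix logA(K, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j)
      logA(k, j) = A(k, j) > 0 ? std::log(A(k, j)) : -1e300;
  for (int k = 0; k < K; ++k) {
    double lb = std::log(std::max(dnorm_pdf(x[0], mu[k], sigma[k]),
                                  1e-300));
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : -1e300) + lb;
  }
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = -1e300;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      double lb = std::log(std::max(dnorm_pdf(x[t], mu[k], sigma[k]),
                                    1e-300));
      delta(t, k) = best + lb;
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  int arg = 0;
  double best = -1e300;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
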