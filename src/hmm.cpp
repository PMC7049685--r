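#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM on one trace.
// Returns the log-likelihood, per-frame posteriors (gamma), summed
// transition posteriors (xi) and the first-frame posterior, all of which
// the R-level EM needs for its M-step. Scaling (per-frame normalization
// of alpha) keeps the recursion in a numerically safe range for traces of
// arbitrary length.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericVector x, NumericVector init,
                              NumericMatrix trans, NumericVector mu,
                              NumericVector sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double b = R::dnorm(x[t], mu[k], sigma[k], 0);
      B(t, k) = (b > 1e-300) ? b : 1e-300;
    }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g <= 0) g = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        z += alpha(t, j) * trans(j, k) * B(t + 1, k) * beta(t + 1, k);
    if (z <= 0) z = 1e-300;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / z;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Log-space Viterbi decoding. Ties are broken toward the lower state
// index (strict improvement required to switch), so equidistant emissions
// idealize to the lower-FRET state.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector init,
                              NumericMatrix trans, NumericVector mu,
                              NumericVector sigma) {
  const int T = x.size(), K = mu.size();
  NumericMatrix logB(T, K), delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      logB(t, k) = R::dnorm(x[t], mu[k], sigma[k], 1);
  for (int k = 0; k < K; ++k)
    delta(0, k) = (init[k] > 0 ? std::log(init[k]) : NEG) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int best_j = 0;
      double best = NEG * 2;
      for (int j = 0; j < K; ++j) {
        double lt = trans(j, k) > 0 ? std::log(trans(j, k)) : NEG;
        double v = delta(t - 1, j) + lt;
        if (v > best) { best = v; best_j = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = best_j;
    }
  }
  IntegerVector path(T);
  int best_k = 0;
  double best = NEG * 2;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); best_k = k; }
  path[T - 1] = best_k;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices for R
}
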