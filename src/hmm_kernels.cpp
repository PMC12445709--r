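#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one trajectory.
//
// B is the T x K matrix of (possibly sub-normalized) emission weights,
// already exponentiated; rescale_log holds per-row log offsets removed
// before exponentiation so that logZ can be reconstructed exactly.
// piv and A may likewise be sub-normalized (variational tilde-parameters);
// the scaling constants absorb the normalization and logZ remains the
// correct variational log-evidence term.
// [[Rcpp::export]]
List fb_scaled(NumericMatrix B, NumericVector rescale_log,
               NumericVector piv, NumericMatrix A) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = piv[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("forward pass underflow at t=1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("forward pass underflow");
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }
  // gamma and pairwise transition expectations
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 1; t < T; ++t) {
    double z = 0.0;
    NumericMatrix xt(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = alpha(t - 1, j) * A(j, k) * B(t, k) * beta(t, k);
        xt(j, k) = v;
        z += v;
      }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += xt(j, k) / z;
  }
  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(c[t]) + rescale_log[t];
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logZ"] = logZ);
}

// Viterbi decoding in log space. logB is T x K, logpi length K, logA K x K.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix logB, NumericVector logpi,
                           NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
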