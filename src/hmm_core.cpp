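#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM with frozen
// emissions. logB: T x K emission log-densities; A: K x K transition
// matrix; pi0: initial distribution. Returns the log-likelihood, the
// posterior state probabilities gamma, the expected transition counts
// (xi sums, the EM numerator for A) and gamma[1, ] for the pi update.

// [[Rcpp::export(name = ".hx_forward_backward")]]
List hx_forward_backward(NumericMatrix logB, NumericMatrix A,
                         NumericVector pi0) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(T, K), beta(T, K), B(T, K), gamma(T, K);
  NumericVector cvec(T), mx(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    mx[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); c += alpha(0, k); }
  cvec[0] = c;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, j);
      double a = s * B(t, j);
      alpha(t, j) = a;
      c += a;
    }
    cvec[t] = c;
    for (int j = 0; j < K; ++j) alpha(t, j) /= c;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / cvec[t + 1];
    }
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]) + mx[t];
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  // expected transition counts: Anum[i,j] = A[i,j] * sum_t alpha[t,i] * W[t+1,j]
  // with W[t,j] = B[t,j] * beta[t,j] / cvec[t]
  NumericMatrix Anum(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      const double w = B(t + 1, j) * beta(t + 1, j) / cvec[t + 1];
      if (w == 0.0) continue;
      for (int i = 0; i < K; ++i) Anum(i, j) += alpha(t, i) * w;
    }
  }
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Anum(i, j) *= A(i, j);
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["Anum"] = Anum);
}

// Full Baum-Welch loop with frozen emissions: estimates only the transition
// matrix and initial distribution. Runs at most max_iter iterations and
// stops when the absolute log-likelihood change drops below tol. Buffers
// are allocated once, so long traces with many EM iterations stay cheap.

// [[Rcpp::export(name = ".hx_em")]]
List hx_em(NumericMatrix logB, NumericMatrix A0, NumericVector pi0_,
           int max_iter, double tol) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> alpha(T * K), beta(T * K), B(T * K), cvec(T), mx(T);
  std::vector<double> A(A0.begin(), A0.end());           // K x K col-major
  std::vector<double> pi0(pi0_.begin(), pi0_.end());
  std::vector<double> Anum(K * K), gamma1(K);
  double ll = 0.0, ll_old = R_NegInf;
  bool converged = false;
  int it = 0;
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    mx[t] = m;
    for (int k = 0; k < K; ++k) B[t + T * k] = std::exp(logB(t, k) - m);
  }
  for (it = 1; it <= max_iter; ++it) {
    // forward
    double c = 0.0;
    for (int k = 0; k < K; ++k) { alpha[T * k] = pi0[k] * B[T * k]; c += alpha[T * k]; }
    cvec[0] = c;
    for (int k = 0; k < K; ++k) alpha[T * k] /= c;
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += alpha[(t - 1) + T * i] * A[i + K * j];
        const double a = s * B[t + T * j];
        alpha[t + T * j] = a;
        c += a;
      }
      cvec[t] = c;
      for (int j = 0; j < K; ++j) alpha[t + T * j] /= c;
    }
    ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(cvec[t]) + mx[t];
    if (std::abs(ll - ll_old) < tol) { converged = true; break; }
    ll_old = ll;
    // backward + accumulators
    for (int k = 0; k < K; ++k) beta[(T - 1) + T * k] = 1.0;
    std::fill(Anum.begin(), Anum.end(), 0.0);
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < K; ++i) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += A[i + K * j] * B[(t + 1) + T * j] * beta[(t + 1) + T * j];
        beta[t + T * i] = s / cvec[t + 1];
      }
      for (int j = 0; j < K; ++j) {
        const double w = B[(t + 1) + T * j] * beta[(t + 1) + T * j] / cvec[t + 1];
        if (w == 0.0) continue;
        for (int i = 0; i < K; ++i) Anum[i + K * j] += alpha[t + T * i] * w;
      }
    }
    // updates
    double gs = 0.0;
    for (int k = 0; k < K; ++k) { gamma1[k] = alpha[T * k] * beta[T * k]; gs += gamma1[k]; }
    for (int k = 0; k < K; ++k) pi0[k] = gamma1[k] / gs;
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += Anum[i + K * j] * A[i + K * j];
      if (rs < 1e-300) rs = 1e-300;
      for (int j = 0; j < K; ++j)
        A[i + K * j] = Anum[i + K * j] * A[i + K * j] / rs;
    }
  }
  NumericMatrix Aout(K, K);
  std::copy(A.begin(), A.end(), Aout.begin());
  return List::create(_["A"] = Aout,
                      _["pi"] = NumericVector(pi0.begin(), pi0.end()),
                      _["loglik"] = ll,
                      _["n_iter"] = std::min(it, max_iter),
                      _["converged"] = converged);
}

// Viterbi decoding in the log domain. Returns the 1-based MAP state path.

// [[Rcpp::export(name = ".hx_viterbi")]]
IntegerVector hx_viterbi(NumericMatrix logB, NumericMatrix logA,
                         NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericVector delta(K), nxt(K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta[k] = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta[0] + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        const double v = delta[i] + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      psi(t, j) = arg;
      nxt[j] = best + logB(t, j);
    }
    for (int j = 0; j < K; ++j) delta[j] = nxt[j];
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta[k] > delta[arg]) arg = k;
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
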