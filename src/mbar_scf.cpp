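#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Self-consistent MBAR iteration, overflow-safe, anchored at state 0.
// u: K x N reduced potentials; n_k: per-state sample counts (zeros
// allowed); f0: start vector; stops when the relative change of f drops
// below tol or after max_iter sweeps.
// [[Rcpp::export(name = ".mbar_scf")]]
List mbar_scf(NumericMatrix u, IntegerVector n_k, NumericVector f0,
              double tol, int max_iter) {
  const int K = u.nrow();
  const int N = u.ncol();
  std::vector<int> sampled;
  std::vector<double> log_nk;
  for (int k = 0; k < K; ++k) {
    if (n_k[k] > 0) {
      sampled.push_back(k);
      log_nk.push_back(std::log((double)n_k[k]));
    }
  }
  const int Ks = (int)sampled.size();
  std::vector<double> f(f0.begin(), f0.end());
  for (int k = K - 1; k >= 0; --k) f[k] -= f[0];
  std::vector<double> log_denom(N), bmax(K), bsum(K), f_new(K);
  int iter = 0;
  bool converged = false;
  double last_resid = R_PosInf;
  while (iter < max_iter) {
    // log_denom[n] = logsumexp_k (log n_k + f_k - u_kn) over sampled k
    for (int n = 0; n < N; ++n) {
      double m = R_NegInf;
      for (int s = 0; s < Ks; ++s) {
        double v = log_nk[s] + f[sampled[s]] - u(sampled[s], n);
        if (v > m) m = v;
      }
      double acc = 0.0;
      for (int s = 0; s < Ks; ++s)
        acc += std::exp(log_nk[s] + f[sampled[s]] - u(sampled[s], n) - m);
      log_denom[n] = m + std::log(acc);
    }
    // f_new[i] = -logsumexp_n (-u_in - log_denom[n])
    for (int i = 0; i < K; ++i) {
      bmax[i] = R_NegInf;
      bsum[i] = 0.0;
    }
    for (int n = 0; n < N; ++n) {
      for (int i = 0; i < K; ++i) {
        double v = -u(i, n) - log_denom[n];
        if (v > bmax[i]) {
          // rescale the running sum to the new maximum
          bsum[i] = bsum[i] * std::exp(bmax[i] - v) + 1.0;
          bmax[i] = v;
        } else {
          bsum[i] += std::exp(v - bmax[i]);
        }
      }
    }
    for (int i = 0; i < K; ++i) f_new[i] = -(bmax[i] + std::log(bsum[i]));
    double anchor = f_new[0];
    double resid = 0.0;
    for (int i = 0; i < K; ++i) {
      f_new[i] -= anchor;
      double r = std::fabs(f_new[i] - f[i]) / (1.0 + std::fabs(f[i]));
      if (r > resid) resid = r;
      f[i] = f_new[i];
    }
    ++iter;
    last_resid = resid;
    if (resid < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["n_iterations"] = iter,
                      _["converged"] = converged,
                      _["residual"] = last_resid);
}

// Fast path of the same iteration: exp(-u) is precomputed once with a
// per-sample shift taken over the sampled states, which cancels exactly
// between the numerator and the denominator of the update, so every sweep
// is pure multiply-add. Returns stable = false when an intermediate loses
// finiteness (extreme potentials); the caller then reruns the log-domain
// kernel above.
// [[Rcpp::export(name = ".mbar_scf_fast")]]
List mbar_scf_fast(NumericMatrix u, IntegerVector n_k, NumericVector f0,
                   double tol, int max_iter) {
  const int K = u.nrow();
  const int N = u.ncol();
  std::vector<int> sampled;
  for (int k = 0; k < K; ++k)
    if (n_k[k] > 0) sampled.push_back(k);
  const int Ks = (int)sampled.size();
  std::vector<double> E((size_t)K * N);
  bool stable = true;
  for (int n = 0; n < N; ++n) {
    double c = R_PosInf;  // min u over sampled states = max of -u
    for (int s = 0; s < Ks; ++s)
      if (u(sampled[s], n) < c) c = u(sampled[s], n);
    for (int i = 0; i < K; ++i) {
      double e = std::exp(c - u(i, n));
      if (!std::isfinite(e)) stable = false;
      E[(size_t)n * K + i] = e;
    }
  }
  std::vector<double> f(f0.begin(), f0.end());
  for (int k = K - 1; k >= 0; --k) f[k] -= f[0];
  std::vector<double> w(Ks), S(K), f_new(K);
  int iter = 0;
  bool converged = false;
  double last_resid = R_PosInf;
  while (stable && iter < max_iter) {
    double fmax = R_NegInf;
    for (int s = 0; s < Ks; ++s)
      if (f[sampled[s]] > fmax) fmax = f[sampled[s]];
    for (int s = 0; s < Ks; ++s)
      w[s] = n_k[sampled[s]] * std::exp(f[sampled[s]] - fmax);
    for (int i = 0; i < K; ++i) S[i] = 0.0;
    for (int n = 0; n < N; ++n) {
      const double *col = &E[(size_t)n * K];
      double D = 0.0;
      for (int s = 0; s < Ks; ++s) D += w[s] * col[sampled[s]];
      if (D <= 0.0 || !std::isfinite(D)) {
        stable = false;
        break;
      }
      double invD = 1.0 / D;
      for (int i = 0; i < K; ++i) S[i] += col[i] * invD;
    }
    if (!stable) break;
    for (int i = 0; i < K; ++i) f_new[i] = -std::log(S[i]);
    double anchor = f_new[0];
    double resid = 0.0;
    for (int i = 0; i < K; ++i) {
      f_new[i] -= anchor;
      if (!std::isfinite(f_new[i])) stable = false;
      double r = std::fabs(f_new[i] - f[i]) / (1.0 + std::fabs(f[i]));
      if (r > resid) resid = r;
      f[i] = f_new[i];
    }
    if (!stable) break;
    ++iter;
    last_resid = resid;
    if (resid < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["n_iterations"] = iter,
                      _["converged"] = converged,
                      _["residual"] = last_resid,
                      _["stable"] = stable);
}
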