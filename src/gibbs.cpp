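#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// doc_id, word_id: flattened token stream (0-based). Each sweep resamples
// every token's topic from p(z = k) proportional to
//   (n_dk + alpha) * (n_kw + beta) / (n_k + V * beta)
// with the token's own assignment removed. Uses R's RNG (unif_rand) so runs
// are reproducible under set.seed().
//
// Returns posterior-mean phi and gamma averaged over post-burn-in sweeps,
// the complete-data log likelihood log p(w | z) per sweep, and optionally
// the full assignment trace (for small-corpus enumeration checks).
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector doc_id, IntegerVector word_id,
                   int D, int V, int K,
                   double alpha, double beta,
                   int iters, int burn_in, bool keep_z_trace) {
  const int N = doc_id.size();
  std::vector<int> z(N);
  std::vector<double> ndk(static_cast<size_t>(D) * K, 0.0);
  std::vector<double> nkw(static_cast<size_t>(K) * V, 0.0);
  std::vector<double> nk(K, 0.0);

  // random initial assignments
  for (int i = 0; i < N; ++i) {
    int k = std::min(K - 1, static_cast<int>(unif_rand() * K));
    z[i] = k;
    ndk[static_cast<size_t>(doc_id[i]) * K + k] += 1.0;
    nkw[static_cast<size_t>(k) * V + word_id[i]] += 1.0;
    nk[k] += 1.0;
  }

  const int n_keep = iters - burn_in;
  NumericMatrix phi_acc(K, V), gamma_acc(D, K);
  NumericVector loglik(iters);
  IntegerMatrix z_trace = keep_z_trace ? IntegerMatrix(n_keep, N)
                                       : IntegerMatrix(0, 0);
  std::vector<double> prob(K);

  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc_id[i], w = word_id[i];
      int k = z[i];
      ndk[static_cast<size_t>(d) * K + k] -= 1.0;
      nkw[static_cast<size_t>(k) * V + w] -= 1.0;
      nk[k] -= 1.0;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double p = (ndk[static_cast<size_t>(d) * K + kk] + alpha) *
                   (nkw[static_cast<size_t>(kk) * V + w] + beta) /
                   (nk[kk] + V * beta);
        prob[kk] = p;
        tot += p;
      }
      double u = unif_rand() * tot, cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += prob[kk];
        if (u <= cum) { k = kk; break; }
      }
      z[i] = k;
      ndk[static_cast<size_t>(d) * K + k] += 1.0;
      nkw[static_cast<size_t>(k) * V + w] += 1.0;
      nk[k] += 1.0;
    }

    // complete-data log likelihood log p(w | z)
    double ll = K * (R::lgammafn(V * beta) - V * R::lgammafn(beta));
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w)
        ll += R::lgammafn(nkw[static_cast<size_t>(k) * V + w] + beta);
      ll -= R::lgammafn(nk[k] + V * beta);
    }
    loglik[it] = ll;

    if (it >= burn_in) {
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + V * beta;
        for (int w = 0; w < V; ++w)
          phi_acc(k, w) += (nkw[static_cast<size_t>(k) * V + w] + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        double nd = 0.0;
        for (int k = 0; k < K; ++k) nd += ndk[static_cast<size_t>(d) * K + k];
        const double denom = nd + K * alpha;
        for (int k = 0; k < K; ++k)
          gamma_acc(d, k) += (ndk[static_cast<size_t>(d) * K + k] + alpha) / denom;
      }
      if (keep_z_trace) {
        for (int i = 0; i < N; ++i) z_trace(it - burn_in, i) = z[i];
      }
    }
  }

  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w) phi_acc(k, w) /= n_keep;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) gamma_acc(d, k) /= n_keep;

  IntegerVector z_final(z.begin(), z.end());
  return List::create(_["phi"] = phi_acc, _["gamma"] = gamma_acc,
                      _["loglik"] = loglik, _["z"] = z_final,
                      _["z_trace"] = z_trace);
}
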