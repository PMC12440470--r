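// Collapsed Gibbs sampling for latent Dirichlet allocation, plus the
// generative sampler used by the synthetic cohort generator.
//
// All randomness comes from a std::mt19937 seeded explicitly, so results are
// reproducible across platforms for a given seed (R's RNG state is not
// touched).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

inline int sample_cat(const std::vector<double> &cum, double u) {
  // cum holds the running (unnormalised) partial sums; u in [0, cum.back())
  int k = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (k >= (int)cum.size()) k = (int)cum.size() - 1;
  return k;
}

} // namespace

// Fit an LDA topic model by collapsed Gibbs sampling.
// tokens: 0-based word ids, documents concatenated; doc_len gives the split.
// Returns the topic-word matrix phi (K x V), rows normalised with the
// smoothing beta folded in: phi[k, w] = (n_kw + beta) / (n_k + V * beta).
// [[Rcpp::export]]
NumericMatrix cpp_lda_fit(IntegerVector tokens, IntegerVector doc_len,
                          int K, int V, double alpha, double beta,
                          int n_iter, int seed) {
  const int N = tokens.size();
  const int D = doc_len.size();
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(N), nk(K, 0);
  // word-major layout keeps the inner topic loop contiguous in memory
  std::vector<int> nwk((size_t)V * K, 0), ndk((size_t)D * K, 0);
  std::vector<int> doc_of(N);
  {
    int pos = 0;
    for (int d = 0; d < D; ++d)
      for (int j = 0; j < doc_len[d]; ++j) doc_of[pos++] = d;
    if (pos != N) stop("doc_len does not sum to length(tokens)");
  }
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif(rng) * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ++nk[k];
    ++nwk[(size_t)tokens[i] * K + k];
    ++ndk[(size_t)doc_of[i] * K + k];
  }

  const double Vbeta = (double)V * beta;
  // reciprocal of the topic normaliser, updated incrementally so the hot
  // loop carries no division
  std::vector<double> recip(K);
  for (int k = 0; k < K; ++k) recip[k] = 1.0 / (nk[k] + Vbeta);
  std::vector<double> cum(K);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = tokens[i], d = doc_of[i];
      int k = z[i];
      const size_t dK = (size_t)d * K, wK = (size_t)w * K;
      --nk[k];
      --nwk[wK + k];
      --ndk[dK + k];
      recip[k] = 1.0 / (nk[k] + Vbeta);
      double tot = 0.0;
      const int *ndkp = &ndk[dK];
      const int *nwkp = &nwk[wK];
      for (int kk = 0; kk < K; ++kk) {
        tot += (ndkp[kk] + alpha) * (nwkp[kk] + beta) * recip[kk];
        cum[kk] = tot;
      }
      k = sample_cat(cum, unif(rng) * tot);
      z[i] = k;
      ++nk[k];
      ++nwk[wK + k];
      ++ndk[dK + k];
      recip[k] = 1.0 / (nk[k] + Vbeta);
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k) {
    const double denom = nk[k] + Vbeta;
    for (int w = 0; w < V; ++w)
      phi(k, w) = (nwk[(size_t)w * K + k] + beta) / denom;
  }
  return phi;
}

// Infer per-document topic proportions for new documents under a fixed
// topic-word matrix phi. Each document is sampled independently with
// n_sweeps Gibbs sweeps over its tokens; theta is averaged over the second
// half of the sweeps. Returns a D x K matrix of proportions (rows sum to 1).
// [[Rcpp::export]]
NumericMatrix cpp_lda_infer(IntegerVector tokens, IntegerVector doc_len,
                            NumericMatrix phi, double alpha,
                            int n_sweeps, int seed) {
  const int K = phi.nrow();
  const int V = phi.ncol();
  const int D = doc_len.size();
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // word-major copy of phi: contiguous access over topics per token
  std::vector<double> phiv((size_t)V * K);
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < K; ++k) phiv[(size_t)w * K + k] = phi(k, w);

  NumericMatrix theta(D, K);
  std::vector<double> cum(K), acc(K), nda(K);
  const int n_avg = std::max(1, n_sweeps / 2);

  int pos = 0;
  for (int d = 0; d < D; ++d) {
    const int len = doc_len[d];
    std::vector<int> zd(len);
    std::fill(nda.begin(), nda.end(), alpha);
    for (int j = 0; j < len; ++j) {
      int k = (int)(unif(rng) * K);
      if (k == K) k = K - 1;
      zd[j] = k;
      nda[k] += 1.0;
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int it = 0; it < n_sweeps; ++it) {
      for (int j = 0; j < len; ++j) {
        const int w = tokens[pos + j];
        int k = zd[j];
        nda[k] -= 1.0;
        const double *pw = &phiv[(size_t)w * K];
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          tot += nda[kk] * pw[kk];
          cum[kk] = tot;
        }
        k = sample_cat(cum, unif(rng) * tot);
        zd[j] = k;
        nda[k] += 1.0;
      }
      if (it >= n_sweeps - n_avg) {
        const double denom = len + K * alpha;
        for (int kk = 0; kk < K; ++kk) acc[kk] += nda[kk] / denom;
      }
    }
    for (int kk = 0; kk < K; ++kk) theta(d, kk) = acc[kk] / n_avg;
    pos += len;
    if (d % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return theta;
}

// Generative sampler for synthetic notes: for each note d draw lens[d]
// tokens by first drawing a topic from theta[d, ] then a word from
// phi[topic, ]. Returns 1-based word ids per note plus the number of tokens
// drawn from the designated signal topics (signal_topics is 1-based).
// [[Rcpp::export]]
List cpp_sample_notes(NumericMatrix theta, NumericMatrix phi,
                      IntegerVector lens, IntegerVector signal_topics,
                      int seed) {
  const int D = theta.nrow();
  const int K = theta.ncol();
  const int V = phi.ncol();
  if (phi.nrow() != K) stop("theta and phi disagree on the number of topics");
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // cumulative word distribution per topic, computed once
  std::vector<double> phic((size_t)K * V);
  for (int k = 0; k < K; ++k) {
    double tot = 0.0;
    for (int w = 0; w < V; ++w) {
      tot += phi(k, w);
      phic[(size_t)k * V + w] = tot;
    }
  }
  std::vector<bool> is_signal(K, false);
  for (int i = 0; i < signal_topics.size(); ++i) {
    const int k = signal_topics[i] - 1;
    if (k < 0 || k >= K) stop("signal topic index out of range");
    is_signal[k] = true;
  }

  List out(D);
  IntegerVector signal_count(D);
  std::vector<double> tcum(K);
  for (int d = 0; d < D; ++d) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      tot += theta(d, k);
      tcum[k] = tot;
    }
    const int len = lens[d];
    IntegerVector words(len);
    int nsig = 0;
    for (int j = 0; j < len; ++j) {
      const int k = sample_cat(tcum, unif(rng) * tot);
      if (is_signal[k]) ++nsig;
      const double *pc = &phic[(size_t)k * V];
      const double u = unif(rng) * pc[V - 1];
      int w = (int)(std::lower_bound(pc, pc + V, u) - pc);
      if (w >= V) w = V - 1;
      words[j] = w + 1;
    }
    out[d] = words;
    signal_count[d] = nsig;
    if (d % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tokens"] = out, _["signal_tokens"] = signal_count);
}
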