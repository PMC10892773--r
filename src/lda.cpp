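#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Self-contained PRNG (splitmix64) so topic sampling is reproducible across
// platforms and independent of R's global RNG state.
namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int sample_cat(const std::vector<double> &w, double total) {
    double u = unif() * total, acc = 0.0;
    for (size_t k = 0; k < w.size(); ++k) {
      acc += w[k];
      if (u <= acc) return (int)k;
    }
    return (int)w.size() - 1;
  }
};

}  // namespace

// Collapsed Gibbs sampler for LDA on a document-term count matrix
// (D x V, non-negative integers).  Returns the topic-word distribution
// phi (K x V, rows of topic-word posterior means) and the training
// document-topic distribution theta (D x K).
// [[Rcpp::export]]
List lda_gibbs_fit(IntegerMatrix dtm, int K, double alpha, double beta,
                   int n_iter, int seed) {
  const int D = dtm.nrow(), V = dtm.ncol();
  // token expansion
  std::vector<int> tok_d, tok_w;
  for (int d = 0; d < D; ++d)
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < dtm(d, v); ++c) {
        tok_d.push_back(d);
        tok_w.push_back(v);
      }
  const size_t N = tok_d.size();
  Rng rng((uint64_t)seed);

  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nkv((size_t)K * V, 0.0),
      nk(K, 0.0);
  for (size_t i = 0; i < N; ++i) {
    int k = (int)(rng.unif() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[(size_t)tok_d[i] * K + k] += 1.0;
    nkv[(size_t)k * V + tok_w[i]] += 1.0;
    nk[k] += 1.0;
  }

  // running averages over the second half of the chain
  std::vector<double> phi_acc((size_t)K * V, 0.0), theta_acc((size_t)D * K, 0.0);
  int n_avg = 0;
  std::vector<double> p(K);
  const double Vbeta = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (size_t i = 0; i < N; ++i) {
      const int d = tok_d[i], w = tok_w[i], old = z[i];
      ndk[(size_t)d * K + old] -= 1.0;
      nkv[(size_t)old * V + w] -= 1.0;
      nk[old] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[(size_t)d * K + k] + alpha) *
               (nkv[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
        tot += p[k];
      }
      const int knew = rng.sample_cat(p, tot);
      z[i] = knew;
      ndk[(size_t)d * K + knew] += 1.0;
      nkv[(size_t)knew * V + w] += 1.0;
      nk[knew] += 1.0;
    }
    if (it >= n_iter / 2) {
      ++n_avg;
      for (size_t j = 0; j < phi_acc.size(); ++j) phi_acc[j] += nkv[j];
      for (size_t j = 0; j < theta_acc.size(); ++j) theta_acc[j] += ndk[j];
    }
  }
  if (n_avg == 0) n_avg = 1;

  NumericMatrix phi(K, V), theta(D, K);
  for (int k = 0; k < K; ++k) {
    double row = 0.0;
    for (int v = 0; v < V; ++v) row += phi_acc[(size_t)k * V + v] / n_avg;
    for (int v = 0; v < V; ++v)
      phi(k, v) = (phi_acc[(size_t)k * V + v] / n_avg + beta) / (row + Vbeta);
  }
  for (int d = 0; d < D; ++d) {
    double nd = 0.0;
    for (int k = 0; k < K; ++k) nd += theta_acc[(size_t)d * K + k] / n_avg;
    for (int k = 0; k < K; ++k)
      theta(d, k) =
          (theta_acc[(size_t)d * K + k] / n_avg + alpha) / (nd + K * alpha);
  }
  return List::create(_["phi"] = phi, _["theta"] = theta);
}

// Fold-in inference of the document-topic distribution for one (possibly
// unseen) document, holding phi fixed.  Averages theta over the second
// half of the chain.
// [[Rcpp::export]]
NumericVector lda_gibbs_transform(NumericMatrix phi, IntegerVector counts,
                                  double alpha, int n_iter, int seed) {
  const int K = phi.nrow(), V = phi.ncol();
  std::vector<int> tok_w;
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < counts[v]; ++c) tok_w.push_back(v);
  const size_t N = tok_w.size();
  NumericVector theta(K);
  if (N == 0) {  // degenerate: caller warns, uniform by convention
    for (int k = 0; k < K; ++k) theta[k] = 1.0 / K;
    return theta;
  }
  Rng rng((uint64_t)seed);
  std::vector<int> z(N);
  std::vector<double> ndk(K, 0.0), p(K);
  for (size_t i = 0; i < N; ++i) {
    int k = (int)(rng.unif() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk[k] += 1.0;
  }
  std::vector<double> acc(K, 0.0);
  int n_avg = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (size_t i = 0; i < N; ++i) {
      const int w = tok_w[i], old = z[i];
      ndk[old] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[k] + alpha) * phi(k, w);
        tot += p[k];
      }
      const int knew = rng.sample_cat(p, tot);
      z[i] = knew;
      ndk[knew] += 1.0;
    }
    if (it >= n_iter / 2) {
      ++n_avg;
      for (int k = 0; k < K; ++k) acc[k] += ndk[k];
    }
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += acc[k] / n_avg + alpha;
  for (int k = 0; k < K; ++k) theta[k] = (acc[k] / n_avg + alpha) / tot;
  return theta;
}
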