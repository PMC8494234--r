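// Collapsed Gibbs sampling for latent Dirichlet allocation on a binary
// cells-by-peaks corpus, plus a fixed-phi sampler for new cells and a
// Chib-style held-out log-likelihood estimator.
//
// All randomness comes from R's RNG (unif_rand), so results are
// bit-reproducible for a given set.seed() when n_workers == 1.
//
// Prior convention: `a` and `b` are the *per-component* Dirichlet weights
// (alpha/K and beta/V under the total-weight convention); `bV` = V * b is
// the total topic-peak prior mass appearing in the denominator.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int sample_discrete(const std::vector<double> &p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export]]
List lda_fit_cpp(List docs, int V, int K, double a, double b,
                 int iterations, int burn_in, int sample_stride,
                 int n_workers, bool track_tokens) {
  int D = docs.size();
  // flatten tokens
  std::vector<int> tok_doc, tok_word;
  for (int d = 0; d < D; ++d) {
    IntegerVector w = docs[d];
    for (int i = 0; i < w.size(); ++i) {
      tok_doc.push_back(d);
      tok_word.push_back(w[i] - 1);
    }
  }
  int N = (int)tok_doc.size();
  double bV = b * V;

  std::vector<int> z(N);
  std::vector<int> nd(D * K, 0), nw(V * K, 0), nk(K, 0);
  for (int i = 0; i < N; ++i) {
    int k = (int)std::floor(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    nd[tok_doc[i] * K + k]++;
    nw[tok_word[i] * K + k]++;
    nk[k]++;
  }

  // token ranges per worker partition (contiguous blocks of documents)
  std::vector<int> part_beg, part_end;
  if (n_workers < 1) n_workers = 1;
  if (n_workers > D) n_workers = D;
  {
    // token index boundaries follow document boundaries
    std::vector<int> doc_first(D + 1, N);
    for (int i = N - 1; i >= 0; --i) doc_first[tok_doc[i]] = i;
    doc_first[D] = N;
    // fill gaps for empty docs
    for (int d = D - 1; d >= 0; --d)
      if (doc_first[d] == N && d + 1 <= D) doc_first[d] = doc_first[d + 1];
    for (int wkr = 0; wkr < n_workers; ++wkr) {
      int d0 = (int)((double)wkr * D / n_workers);
      int d1 = (int)((double)(wkr + 1) * D / n_workers);
      part_beg.push_back(doc_first[d0]);
      part_end.push_back(doc_first[d1]);
    }
  }

  std::vector<double> nd_sum(D * K, 0.0), nw_sum(V * K, 0.0), nk_sum(K, 0.0);
  std::vector<double> tok_freq;
  if (track_tokens) tok_freq.assign((size_t)N * K, 0.0);
  int n_samples = 0;

  std::vector<double> p(K);
  std::vector<int> nw_snap, nk_snap, nw_loc, nk_loc;

  for (int it = 0; it < iterations; ++it) {
    if (n_workers == 1) {
      for (int i = 0; i < N; ++i) {
        int d = tok_doc[i], w = tok_word[i], k = z[i];
        nd[d * K + k]--; nw[w * K + k]--; nk[k]--;
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double val = (nd[d * K + kk] + a) * (nw[w * K + kk] + b) /
                       (nk[kk] + bV);
          p[kk] = val; tot += val;
        }
        k = sample_discrete(p, tot);
        z[i] = k;
        nd[d * K + k]++; nw[w * K + k]++; nk[k]++;
      }
    } else {
      // AD-LDA style: each partition sweeps against a stale snapshot of the
      // word-topic counts; deltas are merged after all partitions finish.
      nw_snap = nw; nk_snap = nk;
      std::vector<long> dnw(V * K, 0), dnk(K, 0);
      for (int wkr = 0; wkr < n_workers; ++wkr) {
        nw_loc = nw_snap; nk_loc = nk_snap;
        for (int i = part_beg[wkr]; i < part_end[wkr]; ++i) {
          int d = tok_doc[i], w = tok_word[i], k = z[i];
          nd[d * K + k]--; nw_loc[w * K + k]--; nk_loc[k]--;
          double tot = 0.0;
          for (int kk = 0; kk < K; ++kk) {
            double val = (nd[d * K + kk] + a) * (nw_loc[w * K + kk] + b) /
                         (nk_loc[kk] + bV);
            p[kk] = val; tot += val;
          }
          k = sample_discrete(p, tot);
          z[i] = k;
          nd[d * K + k]++; nw_loc[w * K + k]++; nk_loc[k]++;
        }
        for (int j = 0; j < V * K; ++j) dnw[j] += nw_loc[j] - nw_snap[j];
        for (int k2 = 0; k2 < K; ++k2) dnk[k2] += nk_loc[k2] - nk_snap[k2];
      }
      for (int j = 0; j < V * K; ++j) nw[j] = nw_snap[j] + (int)dnw[j];
      for (int k2 = 0; k2 < K; ++k2) nk[k2] = nk_snap[k2] + (int)dnk[k2];
    }

    if (it >= burn_in && ((it - burn_in) % sample_stride == 0)) {
      ++n_samples;
      for (int j = 0; j < D * K; ++j) nd_sum[j] += nd[j];
      for (int j = 0; j < V * K; ++j) nw_sum[j] += nw[j];
      for (int k2 = 0; k2 < K; ++k2) nk_sum[k2] += nk[k2];
      if (track_tokens)
        for (int i = 0; i < N; ++i) tok_freq[(size_t)i * K + z[i]] += 1.0;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  if (n_samples == 0) {
    // no post-burn-in samples requested; fall back to the final state
    n_samples = 1;
    for (int j = 0; j < D * K; ++j) nd_sum[j] = nd[j];
    for (int j = 0; j < V * K; ++j) nw_sum[j] = nw[j];
    for (int k2 = 0; k2 < K; ++k2) nk_sum[k2] = nk[k2];
    if (track_tokens)
      for (int i = 0; i < N; ++i) tok_freq[(size_t)i * K + z[i]] = 1.0;
  }

  IntegerMatrix docTopic(D, K), wordTopic(V, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) docTopic(d, k) = nd[d * K + k];
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < K; ++k) wordTopic(w, k) = nw[w * K + k];

  NumericMatrix nd_mean(D, K), nw_mean(V, K);
  NumericVector nk_mean(K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) nd_mean(d, k) = nd_sum[d * K + k] / n_samples;
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < K; ++k) nw_mean(w, k) = nw_sum[w * K + k] / n_samples;
  for (int k = 0; k < K; ++k) nk_mean[k] = nk_sum[k] / n_samples;

  List out = List::create(
      _["docTopic"] = docTopic, _["wordTopic"] = wordTopic,
      _["nd_mean"] = nd_mean, _["nw_mean"] = nw_mean, _["nk_mean"] = nk_mean,
      _["z"] = IntegerVector(z.begin(), z.end()),
      _["token_doc"] = IntegerVector(tok_doc.begin(), tok_doc.end()),
      _["token_word"] = IntegerVector(tok_word.begin(), tok_word.end()),
      _["n_samples"] = n_samples);
  if (track_tokens) {
    NumericMatrix tf(N, K);
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < K; ++k) tf(i, k) = tok_freq[(size_t)i * K + k] / n_samples;
    out["token_freq"] = tf;
  }
  return out;
}

// Gibbs over the tokens of new documents with phi held fixed.
// phi is K x V; returns the prior-smoothed mean theta rows.
// [[Rcpp::export]]
NumericMatrix lda_predict_cpp(List docs, NumericMatrix phi, double a,
                              int iterations, int burn_in, int sample_stride) {
  int D = docs.size();
  int K = phi.nrow();
  NumericMatrix theta(D, K);
  std::vector<double> p(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector w = docs[d];
    int N = w.size();
    if (N == 0) {
      for (int k = 0; k < K; ++k) theta(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> z(N), nk(K, 0);
    for (int i = 0; i < N; ++i) {
      int k = (int)std::floor(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[i] = k; nk[k]++;
    }
    std::vector<double> nk_sum(K, 0.0);
    int n_samples = 0;
    for (int it = 0; it < iterations; ++it) {
      for (int i = 0; i < N; ++i) {
        int k = z[i];
        nk[k]--;
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double val = (nk[kk] + a) * phi(kk, w[i] - 1);
          p[kk] = val; tot += val;
        }
        k = sample_discrete(p, tot);
        z[i] = k; nk[k]++;
      }
      if (it >= burn_in && ((it - burn_in) % sample_stride == 0)) {
        ++n_samples;
        for (int k = 0; k < K; ++k) nk_sum[k] += nk[k];
      }
    }
    if (n_samples == 0) {
      n_samples = 1;
      for (int k = 0; k < K; ++k) nk_sum[k] = nk[k];
    }
    double aK = a * K;
    for (int k = 0; k < K; ++k)
      theta(d, k) = (nk_sum[k] / n_samples + a) / (N + aK);
  }
  return theta;
}

static double log_joint(const std::vector<int> &z, const IntegerVector &w,
                        const NumericMatrix &phi, double a) {
  int K = phi.nrow();
  int N = (int)z.size();
  std::vector<int> nk(K, 0);
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    ll += std::log(phi(z[i], w[i] - 1));
    nk[z[i]]++;
  }
  double aK = a * K;
  ll += std::lgamma(aK) - std::lgamma(aK + N);
  for (int k = 0; k < K; ++k)
    ll += std::lgamma(a + nk[k]) - std::lgamma(a);
  return ll;
}

// log probability of one full sequential Gibbs sweep moving `from` to `to`
static double log_sweep_kernel(const std::vector<int> &from,
                               const std::vector<int> &to,
                               const IntegerVector &w,
                               const NumericMatrix &phi, double a) {
  int K = phi.nrow();
  int N = (int)from.size();
  std::vector<int> nk(K, 0);
  for (int i = 0; i < N; ++i) nk[from[i]]++;
  std::vector<int> cur = from;
  double lp = 0.0;
  for (int i = 0; i < N; ++i) {
    nk[cur[i]]--;
    double tot = 0.0, num = 0.0;
    for (int k = 0; k < K; ++k) {
      double val = (nk[k] + a) * phi(k, w[i] - 1);
      tot += val;
      if (k == to[i]) num = val;
    }
    lp += std::log(num) - std::log(tot);
    cur[i] = to[i];
    nk[cur[i]]++;
  }
  return lp;
}

// Chib-style estimate of log p(w | phi, alpha) for one held-out document.
// Pivot z* is the highest-joint-probability state visited after burn-in;
// log p-hat(z* | w) is the log-mean of the sweep-kernel probabilities
// T(z_s -> z*) over states z_s from the stationary chain.
// [[Rcpp::export]]
double chib_loglik_cpp(IntegerVector w, NumericMatrix phi, double a,
                       int burn_in, int n_samples) {
  int K = phi.nrow();
  int N = w.size();
  std::vector<int> z(N), nk(K, 0);
  std::vector<double> p(K);
  for (int i = 0; i < N; ++i) {
    int k = (int)std::floor(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k; nk[k]++;
  }
  auto sweep = [&]() {
    for (int i = 0; i < N; ++i) {
      int k = z[i];
      nk[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double val = (nk[kk] + a) * phi(kk, w[i] - 1);
        p[kk] = val; tot += val;
      }
      k = sample_discrete(p, tot);
      z[i] = k; nk[k]++;
    }
  };

  std::vector<int> zstar = z;
  double best = R_NegInf;
  for (int it = 0; it < burn_in; ++it) {
    sweep();
    double lj = log_joint(z, w, phi, a);
    if (lj > best) { best = lj; zstar = z; }
  }
  if (!R_FINITE(best)) { zstar = z; best = log_joint(z, w, phi, a); }

  // stationary-chain samples started from the pivot
  z = zstar;
  nk.assign(K, 0);
  for (int i = 0; i < N; ++i) nk[z[i]]++;
  std::vector<double> logT(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    sweep();
    logT[s] = log_sweep_kernel(z, zstar, w, phi, a);
  }
  double m = logT[0];
  for (int s = 1; s < n_samples; ++s) if (logT[s] > m) m = logT[s];
  double acc = 0.0;
  for (int s = 0; s < n_samples; ++s) acc += std::exp(logT[s] - m);
  double log_phat = m + std::log(acc / n_samples);
  return best - log_phat;
}

// Left-to-right sequential estimator (Wallach et al. style cross-check).
// [[Rcpp::export]]
double l2r_loglik_cpp(IntegerVector w, NumericMatrix phi, double a,
                      int n_particles) {
  int K = phi.nrow();
  int N = w.size();
  double aK = a * K;
  std::vector<std::vector<int>> z(n_particles);
  std::vector<std::vector<int>> nk(n_particles, std::vector<int>(K, 0));
  std::vector<double> p(K);
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    double pw = 0.0;
    for (int r = 0; r < n_particles; ++r) {
      // resample earlier positions once (particle rejuvenation)
      for (int j = 0; j < i; ++j) {
        int k = z[r][j];
        nk[r][k]--;
        double tot = 0.0;
        for (int kk = 0; kk < K; ++kk) {
          double val = (nk[r][kk] + a) * phi(kk, w[j] - 1);
          p[kk] = val; tot += val;
        }
        k = sample_discrete(p, tot);
        z[r][j] = k; nk[r][k]++;
      }
      double pi = 0.0, tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        double val = (nk[r][kk] + a) * phi(kk, w[i] - 1);
        p[kk] = val; tot += val;
        pi += (nk[r][kk] + a) / (i + aK) * phi(kk, w[i] - 1);
      }
      pw += pi;
      int k = sample_discrete(p, tot);
      z[r].push_back(k); nk[r][k]++;
    }
    ll += std::log(pw / n_particles);
  }
  return ll;
}
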