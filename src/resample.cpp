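#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resampling cores used by the shuffle-based significance procedures and the
// permutation t-test. All randomness goes through R's RNG (set.seed()
// upstream controls every draw).

static inline int rand_below(int m) {
  int k;
  do {
    k = (int)(unif_rand() * m);
  } while (k >= m); // guard against unif_rand() == 1.0
  return k;
}

// Draw `k` distinct entries from idx[0..n-1] by partial Fisher-Yates; swaps
// are undone afterwards so the pool can be reused across shuffles.
static void sample_distinct(std::vector<int> &idx, int k,
                            std::vector<int> &out, std::vector<int> &swaps) {
  int n = (int)idx.size();
  for (int i = 0; i < k; ++i) {
    int j = i + rand_below(n - i);
    std::swap(idx[i], idx[j]);
    swaps[i] = j;
    out[i] = idx[i];
  }
  for (int i = k - 1; i >= 0; --i) std::swap(idx[i], idx[swaps[i]]);
}

//' @name spncode-internal
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_shuffle_behavior_sums(NumericVector amps,
                                        IntegerVector frame_beh,
                                        int n_beh, int n_shuffles) {
  // amps: event amplitudes; the event positions are re-drawn uniformly
  // without replacement among the labelled frames for each shuffle.
  // frame_beh: 0-based behavior id of every labelled frame.
  const int n_frames = frame_beh.size();
  const int k = amps.size();
  if (k > n_frames) stop("more events than frames");
  NumericMatrix out(n_shuffles, n_beh);
  std::vector<int> idx(n_frames);
  for (int i = 0; i < n_frames; ++i) idx[i] = i;
  std::vector<int> pos(k), swaps(k);
  for (int s = 0; s < n_shuffles; ++s) {
    sample_distinct(idx, k, pos, swaps);
    for (int e = 0; e < k; ++e) {
      int b = frame_beh[pos[e]];
      out(s, b) += amps[e];
    }
  }
  return out;
}

//' @name spncode-internal
//' @keywords internal
// [[Rcpp::export]]
NumericVector cpp_shuffle_occurrence(int n_events, IntegerVector episode_id,
                                     int n_episodes, int n_shuffles) {
  // episode_id: per-frame episode index (1..n_episodes) for frames belonging
  // to the behavior of interest, 0 elsewhere. Returns, per shuffle, the
  // fraction of episodes receiving at least one event.
  const int n_frames = episode_id.size();
  if (n_events > n_frames) stop("more events than frames");
  NumericVector out(n_shuffles);
  std::vector<int> idx(n_frames);
  for (int i = 0; i < n_frames; ++i) idx[i] = i;
  std::vector<int> pos(n_events), swaps(n_events), stamp(n_episodes + 1, -1);
  for (int s = 0; s < n_shuffles; ++s) {
    sample_distinct(idx, n_events, pos, swaps);
    int hit = 0;
    for (int e = 0; e < n_events; ++e) {
      int ep = episode_id[pos[e]];
      if (ep > 0 && stamp[ep] != s) {
        stamp[ep] = s;
        ++hit;
      }
    }
    out[s] = n_episodes > 0 ? (double)hit / n_episodes : NA_REAL;
  }
  return out;
}

//' @name spncode-internal
//' @keywords internal
// [[Rcpp::export]]
NumericVector cpp_perm_t_abs(NumericVector pooled, int n_a, int n_perm) {
  // |t| (pooled-variance two-sample t) for n_perm random relabellings of the
  // pooled sample; the first n_a entries of each relabelling form group A.
  const int n = pooled.size();
  const int n_b = n - n_a;
  if (n_a < 1 || n_b < 1) stop("both groups need at least one sample");
  NumericVector out(n_perm);
  std::vector<double> x(pooled.begin(), pooled.end());
  const double inv_na = 1.0 / n_a, inv_nb = 1.0 / n_b;
  for (int s = 0; s < n_perm; ++s) {
    // full Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rand_below(i + 1);
      std::swap(x[i], x[j]);
    }
    double sa = 0.0, sb = 0.0, ssa = 0.0, ssb = 0.0;
    for (int i = 0; i < n_a; ++i) { sa += x[i]; ssa += x[i] * x[i]; }
    for (int i = n_a; i < n; ++i) { sb += x[i]; ssb += x[i] * x[i]; }
    double ma = sa * inv_na, mb = sb * inv_nb;
    double ss = (ssa - n_a * ma * ma) + (ssb - n_b * mb * mb);
    double df = n - 2.0;
    double se = std::sqrt(std::max(ss, 0.0) / df * (inv_na + inv_nb));
    double diff = ma - mb;
    if (se <= 0.0) {
      out[s] = (std::fabs(diff) <= 0.0) ? 0.0 : R_PosInf;
    } else {
      out[s] = std::fabs(diff / se);
    }
  }
  return out;
}
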