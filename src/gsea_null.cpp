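// Permutation null for the preranked enrichment score.  For each of n_perm
// draws, k hit positions are sampled uniformly without replacement from the
// n ranked positions (scores held fixed) and the signed maximum deviation of
// the weighted running sum is computed from the sorted hit positions alone:
// between hits the walk decays linearly, so its extremes sit immediately
// after a hit (maximum candidates) or immediately before one (minimum
// candidates), with 0 covering both boundaries.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {
struct Rng2 {
  uint64_t state;
  explicit Rng2(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};
} // namespace

// [[Rcpp::export(name = ".gsea_null_es")]]
NumericVector gsea_null_es(NumericVector scores, int k, int n_perm,
                           double weight, double seed) {
  const int n = scores.size();
  if (k < 1 || k >= n) stop("need 1 <= k < length(scores)");
  Rng2 rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 17ULL);

  std::vector<int> pool(n);
  std::vector<int> pos(k);
  std::vector<double> w(k);
  NumericVector out(n_perm);

  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int j = 0; j < k; ++j) {
      int r = j + rng.below(n - j);
      std::swap(pool[j], pool[r]);
      pos[j] = pool[j];
    }
    std::sort(pos.begin(), pos.begin() + k);

    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      w[j] = std::pow(std::fabs(scores[pos[j]]), weight);
      tot += w[j];
    }
    const double nk = static_cast<double>(n - k);
    double cw = 0.0, maxc = 0.0, minc = 0.0;
    for (int j = 0; j < k; ++j) {
      const double drop = (pos[j] - j) / nk;
      const double frac_before = (tot > 0.0) ? cw / tot
                                             : static_cast<double>(j) / k;
      const double before = frac_before - drop;
      if (before < minc) minc = before;
      cw += w[j];
      const double frac_after = (tot > 0.0) ? cw / tot
                                            : static_cast<double>(j + 1) / k;
      const double after = frac_after - drop;
      if (after > maxc) maxc = after;
    }
    out[b] = (maxc >= -minc) ? maxc : minc;
  }
  return out;
}
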