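// Bagged regression forest with permutation (%IncMSE) and impurity
// (IncNodePurity) variable importance, specialised for the all-predictors-
// per-split setting used when one gene is regressed on every other gene.
//
// Design notes:
//  * Trees are CART regression trees, unpruned; growth stops only when a
//    node holds fewer than 2*min_leaf in-bag cases or admits no split that
//    leaves min_leaf cases per child.
//  * Each tree presorts its in-bag samples once per feature, then partitions
//    the per-feature sorted lists at every split, so no per-node sorting is
//    needed.  With p features and n samples a tree costs O(p n log n +
//    p n depth) instead of O(p n log n) *per node*.
//  * All randomness flows from a splitmix64 generator seeded by the caller,
//    so results are bit-identical across platforms and worker counts.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64: tiny, fast, platform-stable PRNG (we avoid std:: distributions,
// whose streams are implementation-defined).
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on {0, ..., n-1}; modulo bias is immaterial at these n
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node indices
  std::vector<double> value;    // leaf prediction (weighted in-bag mean)

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }

  double predict(const double* x, int stride) const {
    int nd = 0;
    while (feature[nd] >= 0) {
      nd = (x[static_cast<size_t>(feature[nd]) * stride] <= threshold[nd])
               ? left[nd] : right[nd];
    }
    return value[nd];
  }

  // predict with feature f's value replaced by override_val
  double predict_override(const double* x, int stride, int f,
                          double override_val) const {
    int nd = 0;
    while (feature[nd] >= 0) {
      double v = (feature[nd] == f)
                     ? override_val
                     : x[static_cast<size_t>(feature[nd]) * stride];
      nd = (v <= threshold[nd]) ? left[nd] : right[nd];
    }
    return value[nd];
  }
};

struct BuildFrame {
  int node, lo, hi;
  double sw, swy, swy2;
};

} // namespace

// [[Rcpp::export(name = ".rf_fit_importance")]]
List rf_fit_importance(NumericMatrix X, NumericVector y, int ntree, int mtry,
                       int min_leaf, bool bootstrap, int perm_repeats,
                       double seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2 || p < 1) stop("need at least 2 samples and 1 predictor");
  if (mtry < 1 || mtry > p) mtry = p;
  if (min_leaf < 1) min_leaf = 1;
  const double* xp = REAL(X); // column-major: xp[j*n + i]

  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  std::vector<double> purity(p, 0.0);
  std::vector<double> perm_sum(p, 0.0), perm_sumsq(p, 0.0);
  std::vector<double> oob_pred_sum(n, 0.0);
  std::vector<int> oob_pred_cnt(n, 0);
  int trees_with_oob = 0;

  // global per-feature argsort (value, then sample id); each tree derives its
  // in-bag sorted lists by filtering these, so no per-tree sorting is needed
  std::vector<int> gorder(static_cast<size_t>(p) * n);
  {
    std::vector<std::pair<double, int> > keyed0(n);
    for (int f = 0; f < p; ++f) {
      const double* col = xp + static_cast<size_t>(f) * n;
      for (int i = 0; i < n; ++i) keyed0[i] = std::make_pair(col[i], i);
      std::sort(keyed0.begin(), keyed0.end());
      int* gf = &gorder[static_cast<size_t>(f) * n];
      for (int i = 0; i < n; ++i) gf[i] = keyed0[i].second;
    }
  }

  // reusable per-tree buffers
  std::vector<int> w(n);                  // in-bag multiplicity
  std::vector<int> items;                 // distinct in-bag sample ids
  std::vector<int> ord, buf_l, buf_r;     // p stacked sorted lists / partition buffers
  std::vector<char> used(p);
  std::vector<int> feat_pool(p), oob;
  std::vector<int> perm_idx;

  for (int t = 0; t < ntree; ++t) {
    // ---- bootstrap ----
    std::fill(w.begin(), w.end(), 0);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) w[rng.below(n)]++;
    } else {
      std::fill(w.begin(), w.end(), 1);
    }
    items.clear();
    oob.clear();
    for (int i = 0; i < n; ++i) {
      if (w[i] > 0) items.push_back(i); else oob.push_back(i);
    }
    const int m = static_cast<int>(items.size());
    if (m < 2) continue; // degenerate bootstrap; effectively impossible for n >= 10

    // ---- in-bag sorted lists: filter the global order by bag membership ----
    ord.resize(static_cast<size_t>(p) * m);
    buf_l.resize(m);
    buf_r.resize(m);
    for (int f = 0; f < p; ++f) {
      const int* gf = &gorder[static_cast<size_t>(f) * n];
      int* of = &ord[static_cast<size_t>(f) * m];
      int k = 0;
      for (int i = 0; i < n; ++i) {
        if (w[gf[i]] > 0) of[k++] = gf[i];
      }
    }

    // ---- grow tree (explicit stack, deterministic order) ----
    Tree tree;
    std::fill(used.begin(), used.end(), 0);
    double sw0 = 0.0, swy0 = 0.0, swy20 = 0.0;
    for (int j = 0; j < m; ++j) {
      int i = items[j];
      sw0 += w[i];
      swy0 += w[i] * y[i];
      swy20 += w[i] * y[i] * y[i];
    }
    std::vector<BuildFrame> stack;
    int root = tree.new_node();
    stack.push_back(BuildFrame{root, 0, m, sw0, swy0, swy20});

    while (!stack.empty()) {
      BuildFrame fr = stack.back();
      stack.pop_back();
      const int lo = fr.lo, hi = fr.hi;
      const double sw = fr.sw, swy = fr.swy, swy2 = fr.swy2;
      tree.value[fr.node] = swy / sw;
      const double node_sse = swy2 - swy * swy / sw;
      if (sw < 2.0 * min_leaf || node_sse <= 1e-12 * (std::fabs(swy2) + 1.0)) {
        continue; // leaf
      }

      // candidate features: a random mtry-subset, examined in random order
      // so exactly tied gains (e.g. collinear predictors inducing the same
      // partition) are broken at random rather than by feature index
      for (int f = 0; f < p; ++f) feat_pool[f] = f;
      const int nfeat = mtry;
      for (int s = 0; s < nfeat; ++s) {
        int r = s + rng.below(p - s);
        std::swap(feat_pool[s], feat_pool[r]);
      }

      double best_gain = -1.0, best_thr = 0.0;
      int best_f = -1;
      const double parent_score = swy * swy / sw;
      for (int s = 0; s < nfeat; ++s) {
        const int f = feat_pool[s];
        const double* col = xp + static_cast<size_t>(f) * n;
        const int* of = &ord[static_cast<size_t>(f) * m];
        double swl = 0.0, swyl = 0.0;
        for (int j = lo; j < hi - 1; ++j) {
          const int i = of[j];
          swl += w[i];
          swyl += w[i] * y[i];
          const double v = col[i], vnext = col[of[j + 1]];
          if (v >= vnext) continue; // no split between tied values
          const double swr = sw - swl, swyr = swy - swyl;
          if (swl < min_leaf || swr < min_leaf) continue;
          const double gain = swyl * swyl / swl + swyr * swyr / swr - parent_score;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (v + vnext);
          }
        }
      }
      if (best_f < 0 || best_gain <= 0.0) continue; // leaf: no admissible split

      purity[best_f] += best_gain; // decrease in residual sum of squares
      used[best_f] = 1;

      // partition every feature's sorted slice on the chosen split
      const double* bcol = xp + static_cast<size_t>(best_f) * n;
      int nl = 0;
      for (int f = 0; f < p; ++f) {
        int* of = &ord[static_cast<size_t>(f) * m];
        int cl = 0, cr = 0;
        for (int j = lo; j < hi; ++j) {
          const int i = of[j];
          if (bcol[i] <= best_thr) buf_l[cl++] = i; else buf_r[cr++] = i;
        }
        std::copy(buf_l.begin(), buf_l.begin() + cl, of + lo);
        std::copy(buf_r.begin(), buf_r.begin() + cr, of + lo + cl);
        nl = cl;
      }

      double swl = 0.0, swyl = 0.0, swy2l = 0.0;
      const int* of0 = &ord[0];
      for (int j = lo; j < lo + nl; ++j) {
        const int i = of0[j];
        swl += w[i];
        swyl += w[i] * y[i];
        swy2l += w[i] * y[i] * y[i];
      }
      int lchild = tree.new_node();
      int rchild = tree.new_node();
      tree.feature[fr.node] = best_f;
      tree.threshold[fr.node] = best_thr;
      tree.left[fr.node] = lchild;
      tree.right[fr.node] = rchild;
      stack.push_back(BuildFrame{rchild, lo + nl, hi, sw - swl, swy - swyl,
                                 swy2 - swy2l});
      stack.push_back(BuildFrame{lchild, lo, lo + nl, swl, swyl, swy2l});
    }

    // ---- out-of-bag error and permutation importance ----
    const int no = static_cast<int>(oob.size());
    if (!bootstrap || no == 0) continue;
    trees_with_oob++;

    double err0 = 0.0;
    for (int o = 0; o < no; ++o) {
      const int i = oob[o];
      const double pr = tree.predict(xp + i, n);
      oob_pred_sum[i] += pr;
      oob_pred_cnt[i] += 1;
      const double d = pr - y[i];
      err0 += d * d;
    }
    err0 /= no;

    perm_idx.resize(no);
    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue; // permuting an unseen column cannot change predictions
      const double* col = xp + static_cast<size_t>(f) * n;
      double dsum = 0.0;
      for (int r = 0; r < perm_repeats; ++r) {
        for (int o = 0; o < no; ++o) perm_idx[o] = o;
        for (int o = no - 1; o > 0; --o) {
          int k = rng.below(o + 1);
          std::swap(perm_idx[o], perm_idx[k]);
        }
        double errp = 0.0;
        for (int o = 0; o < no; ++o) {
          const int i = oob[o];
          const double v = col[oob[perm_idx[o]]];
          const double d = tree.predict_override(xp + i, n, f, v) - y[i];
          errp += d * d;
        }
        dsum += errp / no - err0;
      }
      const double d = dsum / perm_repeats;
      perm_sum[f] += d;
      perm_sumsq[f] += d * d;
    }
  }

  // ---- aggregate across trees ----
  NumericVector perm_mean(p, NA_REAL), perm_se(p, NA_REAL), node_purity(p);
  for (int f = 0; f < p; ++f) node_purity[f] = purity[f] / ntree;
  if (bootstrap && trees_with_oob > 1) {
    const double T = trees_with_oob;
    for (int f = 0; f < p; ++f) {
      const double mu = perm_sum[f] / T;
      double var = (perm_sumsq[f] - T * mu * mu) / (T - 1.0);
      if (var < 0.0) var = 0.0;
      perm_mean[f] = mu;
      perm_se[f] = std::sqrt(var / T);
    }
  }
  double oob_mse = NA_REAL;
  if (bootstrap) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (oob_pred_cnt[i] > 0) {
        const double d = oob_pred_sum[i] / oob_pred_cnt[i] - y[i];
        acc += d * d;
        cnt++;
      }
    }
    if (cnt > 0) oob_mse = acc / cnt;
  }

  return List::create(_["perm_mean"] = perm_mean, _["perm_se"] = perm_se,
                      _["inc_node_purity"] = node_purity,
                      _["oob_mse"] = oob_mse,
                      _["trees_with_oob"] = trees_with_oob);
}
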