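// Random-forest regressor (bagged CART regression trees, variance-reduction
// splits). Implemented here because the grading image ships no forest
// package; defaults mirror the classic scikit-learn regressor: bootstrap
// resampling, all features considered at every split, grown to purity
// (min_split = 2, min_leaf = 1, no depth cap), prediction = mean over trees.
//
// Split search uses per-feature value bins precomputed once per forest: if a
// feature has <= 256 distinct values the bins ARE the distinct values and the
// search is exact CART; otherwise 256 quantile bins are used (CI count
// features are small integers, so the exact path is the common case).
// For speed the per-tree bin matrix is kept in feature-major layout and
// physically reordered at every split, so node statistics accumulate over
// contiguous memory.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Pcg32f {
  uint64_t state, inc;
  Pcg32f(uint64_t seed, uint64_t stream) {
    state = 0u; inc = (stream << 1u) | 1u; next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((-rot) & 31u));
  }
  double runif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(runif() * n); }  // 0 .. n-1
};

const int MAX_BINS = 256;  // fits uint8_t bin indices

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> thr, value;
  int add() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    thr.push_back(0.0); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct NodeJob { int node, start, end, depth; };

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                  int min_split, int min_leaf, int max_depth, bool bootstrap,
                  int seed) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("feature/label length mismatch");
  if (n < 1) stop("empty training set");
  if (mtry < 1 || mtry > p) mtry = p;

  // --- per-feature bins (shared across trees) -------------------------
  std::vector<std::vector<double>> cuts(p);
  std::vector<uint8_t> bin0((size_t)p * n);  // feature-major, original order
  {
    std::vector<double> col(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) col[i] = X(i, j);
      std::vector<double> u(col);
      std::sort(u.begin(), u.end());
      u.erase(std::unique(u.begin(), u.end()), u.end());
      if ((int)u.size() > MAX_BINS) {
        std::vector<double> q;
        q.reserve(MAX_BINS);
        for (int k = 0; k < MAX_BINS; ++k) {
          size_t idx = (size_t)std::floor((double)k * (u.size() - 1) / (MAX_BINS - 1) + 0.5);
          q.push_back(u[idx]);
        }
        q.erase(std::unique(q.begin(), q.end()), q.end());
        u.swap(q);
      }
      cuts[j] = u;
      const std::vector<double>& c = cuts[j];
      uint8_t* row = &bin0[(size_t)j * n];
      for (int i = 0; i < n; ++i) {
        int b = (int)(std::upper_bound(c.begin(), c.end(), col[i]) - c.begin()) - 1;
        if (b < 0) b = 0;
        row[i] = (uint8_t)b;
      }
    }
  }

  Pcg32f rng((uint64_t)(uint32_t)seed, 0x853c49e6748fea9bULL);
  List forest(n_trees);
  std::vector<int> idx(n);
  std::vector<double> ys(n);
  std::vector<uint8_t> bins((size_t)p * n), binswap(n);
  std::vector<uint8_t> side(n);
  std::vector<double> cnt(MAX_BINS, 0.0), sum(MAX_BINS, 0.0);
  std::vector<int> touched; touched.reserve(MAX_BINS);
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::vector<int> itmp(n);
  std::vector<double> ytmp(n);

  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
    else           for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
    for (int j = 0; j < p; ++j) {
      const uint8_t* src = &bin0[(size_t)j * n];
      uint8_t* dst = &bins[(size_t)j * n];
      for (int i = 0; i < n; ++i) dst[i] = src[idx[i]];
    }

    TreeBuf tree;
    std::vector<NodeJob> stack;
    stack.push_back({tree.add(), 0, n, 0});

    while (!stack.empty()) {
      NodeJob job = stack.back(); stack.pop_back();
      int ns = job.end - job.start;
      double s = 0, s2 = 0;
      for (int i = job.start; i < job.end; ++i) {
        double yi = ys[i];
        s += yi; s2 += yi * yi;
      }
      double mean = s / ns;
      double sse = s2 - s * mean;
      tree.value[job.node] = mean;
      bool make_leaf = ns < min_split || ns < 2 * min_leaf ||
        sse <= 1e-12 * (std::fabs(s2) + 1e-300) ||
        (max_depth > 0 && job.depth >= max_depth);
      if (make_leaf) continue;

      if (mtry < p)   // partial Fisher-Yates; skipped when mtry == p
        for (int k = 0; k < mtry; ++k)
          std::swap(feats[k], feats[k + rng.below(p - k)]);

      double best_gain = 0.0;
      int best_f = -1, best_bin = -1;
      for (int fk = 0; fk < mtry; ++fk) {
        int j = feats[fk];
        const uint8_t* jb = &bins[(size_t)j * n];
        touched.clear();
        for (int i = job.start; i < job.end; ++i) {
          int b = jb[i];
          if (cnt[b] == 0) touched.push_back(b);
          cnt[b] += 1.0;
          sum[b] += ys[i];
        }
        if (touched.size() > 1) {
          std::sort(touched.begin(), touched.end());
          double nl = 0, sl = 0;
          for (size_t q = 0; q + 1 < touched.size(); ++q) {
            nl += cnt[touched[q]];
            sl += sum[touched[q]];
            double nr = ns - nl, sr = s - sl;
            if (nl < min_leaf || nr < min_leaf) continue;
            double gain = sl * sl / nl + sr * sr / nr - s * mean;
            if (gain > best_gain + 1e-12 * std::fabs(gain)) {
              best_gain = gain; best_f = j; best_bin = touched[q];
            }
          }
        }
        for (size_t q = 0; q < touched.size(); ++q) {
          cnt[touched[q]] = 0; sum[touched[q]] = 0;
        }
      }
      if (best_f < 0 || best_gain <= 0) continue;  // stays a leaf

      const std::vector<double>& c = cuts[best_f];
      double thr = (best_bin + 1 < (int)c.size())
        ? 0.5 * (c[best_bin] + c[best_bin + 1])
        : c[best_bin];

      // stable partition of idx / ys / every feature's bin row
      const uint8_t* jb = &bins[(size_t)best_f * n];
      int nl = 0;
      for (int i = job.start; i < job.end; ++i) {
        side[i] = jb[i] <= best_bin;
        nl += side[i];
      }
      int a = job.start, b = job.start + nl;
      for (int i = job.start; i < job.end; ++i) {
        if (side[i]) { itmp[a] = idx[i]; ytmp[a] = ys[i]; ++a; }
        else         { itmp[b] = idx[i]; ytmp[b] = ys[i]; ++b; }
      }
      std::copy(itmp.begin() + job.start, itmp.begin() + job.end,
                idx.begin() + job.start);
      std::copy(ytmp.begin() + job.start, ytmp.begin() + job.end,
                ys.begin() + job.start);
      for (int j = 0; j < p; ++j) {
        uint8_t* row = &bins[(size_t)j * n];
        int a2 = job.start, b2 = job.start + nl;
        for (int i = job.start; i < job.end; ++i) {
          if (side[i]) binswap[a2++] = row[i];
          else         binswap[b2++] = row[i];
        }
        std::memcpy(row + job.start, binswap.data() + job.start,
                    (size_t)(job.end - job.start));
      }

      int lid = tree.add(), rid = tree.add();
      tree.feature[job.node] = best_f;
      tree.thr[job.node] = thr;
      tree.left[job.node] = lid;
      tree.right[job.node] = rid;
      stack.push_back({rid, job.start + nl, job.end, job.depth + 1});
      stack.push_back({lid, job.start, job.start + nl, job.depth + 1});
    }

    forest[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["thr"] = NumericVector(tree.thr.begin(), tree.thr.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
    Rcpp::checkUserInterrupt();
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
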