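#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimal CART engine for binary classification on all-numeric feature
// matrices: Gini impurity, exhaustive midpoint splits, optional bootstrap
// resampling and per-node feature subsampling (mtry), so a single tree
// (mtry = p, no bootstrap) and a random forest (mtry = floor(sqrt(p)),
// bootstrap) share one code path. Leaves store the class-1 fraction, and
// forest predictions average leaf fractions over trees, giving a
// probability-like score suitable for ROC ranking.
//
// Randomness uses an internal xorshift generator seeded from R so results
// are bit-reproducible across platforms independently of R's RNG state.

namespace {

struct Node {
  int feat;     // -1 for leaf
  double thr;   // split: x[feat] <= thr goes left
  int left, right;
  double prob;  // class-1 fraction at the node
};

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // modulo bias is negligible for the small n used here and keeps the
  // draw implementation-defined-behaviour free (unlike std::*_distribution)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, minsplit;
  XorShift64& rng;
  std::vector<Node> nodes;
  std::vector<int> feats;                  // scratch for feature subsampling
  std::vector<std::pair<double,int> > buf; // scratch (value, label)

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int minsplit_, XorShift64& rng_)
      : X(X_), y(y_), mtry(mtry_), minsplit(minsplit_), rng(rng_) {
    feats.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feats[j] = j;
  }

  int grow(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo, pos = 0;
    for (int i = lo; i < hi; ++i) pos += y[idx[i]];
    Node nd;
    nd.feat = -1; nd.thr = 0.0; nd.left = nd.right = -1;
    nd.prob = static_cast<double>(pos) / n;
    if (pos == 0 || pos == n || n < minsplit) {
      nodes.push_back(nd);
      return static_cast<int>(nodes.size()) - 1;
    }

    // partial Fisher-Yates: first mtry entries of feats are the candidates
    int p = X.ncol();
    for (int j = 0; j < mtry; ++j) std::swap(feats[j], feats[j + rng.below(p - j)]);

    double best_gain = 1e-12, parent = static_cast<double>(pos) * (n - pos) / n;
    int best_feat = -1;
    double best_thr = 0.0;
    for (int j = 0; j < mtry; ++j) {
      int f = feats[j];
      buf.clear();
      for (int i = lo; i < hi; ++i) buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(buf.begin(), buf.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;
        int nl = i + 1, nr = n - nl, rpos = pos - lpos;
        // parent weighted-Gini minus children, up to a factor of 2/n
        double gain = parent
          - static_cast<double>(lpos) * (nl - lpos) / nl
          - static_cast<double>(rpos) * (nr - rpos) / nr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = buf[i].first / 2.0 + buf[i + 1].first / 2.0;
        }
      }
    }
    if (best_feat < 0) { // constant candidate features: make a leaf
      nodes.push_back(nd);
      return static_cast<int>(nodes.size()) - 1;
    }

    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);

    nd.feat = best_feat;
    nd.thr = best_thr;
    nodes.push_back(nd);
    int self = static_cast<int>(nodes.size()) - 1;
    int l = grow(idx, lo, mid);
    int r = grow(idx, mid, hi);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

double predict_one(const std::vector<Node>& nodes, int root,
                   const NumericMatrix& X, int row) {
  int cur = root;
  while (nodes[cur].feat >= 0)
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left
                                                      : nodes[cur].right;
  return nodes[cur].prob;
}

} // namespace

// [[Rcpp::export(name = ".cart_fit_predict")]]
NumericVector cart_fit_predict(NumericMatrix Xtrain, IntegerVector y,
                               NumericMatrix Xtest, int ntree, int mtry,
                               int minsplit, bool bootstrap, double seed) {
  int n = Xtrain.nrow(), m = Xtest.nrow(), p = Xtrain.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(Xtrain)");
  if (Xtest.ncol() != p) stop("train/test feature count mismatch");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  for (int i = 0; i < n; ++i)
    if (y[i] != 0 && y[i] != 1) stop("y must be 0/1");

  NumericVector out(m);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    XorShift64 rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL * (t + 1));
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Grower g(Xtrain, y, mtry, minsplit, rng);
    std::vector<int> span(idx);
    int root = g.grow(span, 0, n);
    for (int i = 0; i < m; ++i) out[i] += predict_one(g.nodes, root, Xtest, i);
  }
  for (int i = 0; i < m; ++i) out[i] /= ntree;
  return out;
}
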