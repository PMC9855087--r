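// Multi-output regression random forest + exact interventional Shapley values.
//
// The forest minimises the summed per-output squared error (variance
// reduction aggregated over all outputs at every split), so one ensemble
// jointly predicts every circuit activity. Shapley values are computed
// exactly per (sample, background point) pair by enumerating, for each tree
// leaf, the features whose split constraints are satisfied only by the
// foreground (set A) or only by the background (set B); the indicator game
// 1[A subset of S, B disjoint from S] has a closed-form Shapley value, so no
// sampling is involved and local accuracy holds to machine precision.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<std::vector<double>> value; // leaf: C outputs (empty internal)
};

// splitmix-style deterministic generator (no library distributions, so
// results are identical across standard libraries / platforms)
struct Rng {
  std::uint64_t s;
  explicit Rng(std::uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  std::uint64_t next() {
    std::uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (std::uint64_t)n); }
};

struct Builder {
  const NumericMatrix& X;          // n x d, column-major
  const std::vector<double>& Yt;   // C x n, column per sample (contiguous)
  int n_all, d, C;
  int mtry, max_depth, min_split;
  Rng rng;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const std::vector<double>& Yt_, int C_,
          int mtry_, int max_depth_, int min_split_, std::uint64_t seed)
      : X(X_), Yt(Yt_), n_all(X_.nrow()), d(X_.ncol()), C(C_), mtry(mtry_),
        max_depth(max_depth_), min_split(min_split_), rng(seed) {
    feat_pool.resize(d);
    for (int j = 0; j < d; ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<int>& idx) {
    std::vector<double> mu(C, 0.0);
    for (int i : idx) {
      const double* y = &Yt[(size_t)i * C];
      for (int c = 0; c < C; ++c) mu[c] += y[c];
    }
    for (int c = 0; c < C; ++c) mu[c] /= idx.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(std::move(mu));
    return (int)tree.feature.size() - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    const int n = (int)idx.size();
    bool pure = true;
    {
      const double* y0 = &Yt[(size_t)idx[0] * C];
      for (size_t k = 1; k < idx.size() && pure; ++k) {
        const double* y = &Yt[(size_t)idx[k] * C];
        for (int c = 0; c < C; ++c)
          if (y[c] != y0[c]) { pure = false; break; }
      }
    }
    if (n < min_split || pure || (max_depth > 0 && depth >= max_depth))
      return make_leaf(idx);

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int k = 0; k < mtry; ++k)
      std::swap(feat_pool[k], feat_pool[k + rng.below(d - k)]);

    double best_gain = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> order(idx);
    std::vector<double> suml(C), sumtot(C, 0.0);
    for (int i : idx) {
      const double* y = &Yt[(size_t)i * C];
      for (int c = 0; c < C; ++c) sumtot[c] += y[c];
    }

    for (int k = 0; k < mtry; ++k) {
      const int f = feat_pool[k];
      const double* xf = &X(0, f);
      std::sort(order.begin(), order.end(),
                [xf](int a, int b) { return xf[a] < xf[b]; });
      if (xf[order.front()] == xf[order.back()]) continue;
      std::fill(suml.begin(), suml.end(), 0.0);
      for (int i = 0; i < n - 1; ++i) {
        const int s = order[i];
        const double* y = &Yt[(size_t)s * C];
        for (int c = 0; c < C; ++c) suml[c] += y[c];
        if (xf[order[i + 1]] == xf[s]) continue; // not a valid cut
        double gain = 0.0;
        const double nl = i + 1, nr = n - i - 1;
        for (int c = 0; c < C; ++c) {
          const double sl = suml[c], sr = sumtot[c] - sl;
          gain += sl * sl / nl + sr * sr / nr;
        }
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xf[s] + xf[order[i + 1]]);
        }
      }
    }
    if (best_f < 0) return make_leaf(idx); // all sampled features constant

    const double* xb = &X(0, best_f);
    std::vector<int> li, ri;
    for (int i : idx) (xb[i] <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(idx);

    const int me = (int)tree.feature.size();
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.emplace_back();
    const int l = build(li, depth + 1);
    tree.left[me] = l;
    const int r = build(ri, depth + 1);
    tree.right[me] = r;
    return me;
  }
};

Tree list_to_tree(const List& tl) {
  Tree t;
  IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"];
  NumericVector thr = tl["threshold"];
  NumericMatrix v = tl["value"];
  const int n = f.size(), C = v.ncol();
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(thr.begin(), thr.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.value.resize(n);
  for (int i = 0; i < n; ++i)
    if (t.feature[i] < 0) {
      t.value[i].resize(C);
      for (int c = 0; c < C; ++c) t.value[i][c] = v(i, c);
    }
  return t;
}

inline const std::vector<double>& tree_predict(const Tree& t, const double* x) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (x[t.feature[node]] <= t.threshold[node]) ? t.left[node]
                                                     : t.right[node];
  return t.value[node];
}

// row i of a column-major matrix into a contiguous buffer
inline void copy_row(const NumericMatrix& M, int i, std::vector<double>& buf) {
  const int d = M.ncol(), n = M.nrow();
  const double* p = &M(0, 0);
  for (int j = 0; j < d; ++j) buf[j] = p[i + (size_t)n * j];
}

// Shapley weights of the indicator game u_{A,B}(S) = 1[A in S, B disj S]
// over d players: WP(a,b) for members of A (positive), WM(a,b) magnitude for
// members of B (negative).
struct ShapWeights {
  int d;
  std::vector<double> wp, wm; // (d+1) x (d+1), [a*(d+1)+b]
  explicit ShapWeights(int d_) : d(d_), wp((d + 1) * (d + 1), 0.0),
                                 wm((d + 1) * (d + 1), 0.0) {
    std::vector<double> w(d); // w(s) = s!(d-1-s)!/d!
    for (int s = 0; s < d; ++s)
      w[s] = std::exp(std::lgamma(s + 1.0) + std::lgamma((double)d - s) -
                      std::lgamma(d + 1.0));
    for (int a = 0; a <= d; ++a)
      for (int b = 0; a + b <= d; ++b) {
        const int m = d - a - b;
        double sp = 0.0, sm = 0.0;
        for (int j = 0; j <= m; ++j) {
          const double cmj = std::exp(std::lgamma(m + 1.0) -
                                      std::lgamma(j + 1.0) -
                                      std::lgamma(m - j + 1.0));
          if (a >= 1) sp += cmj * w[a - 1 + j];
          if (b >= 1) sm += cmj * w[a + j];
        }
        wp[a * (d + 1) + b] = sp;
        wm[a * (d + 1) + b] = sm;
      }
  }
};

struct ShapWalker {
  const Tree* t;
  const ShapWeights& W;
  int d, C;
  const double* x;
  const double* z;
  std::vector<int> state;                // 0 unused, 1 x-side, 2 z-side
  std::vector<std::pair<int, int>> path; // (feature, side)
  double* phi;                           // d x C slab (feature-major)

  ShapWalker(const ShapWeights& W_, int d_, int C_)
      : t(nullptr), W(W_), d(d_), C(C_), state(d_, 0) {
    path.reserve(d_);
  }

  void leaf(int node, int a, int b) {
    const double wplus = W.wp[a * (d + 1) + b];
    const double wminus = W.wm[a * (d + 1) + b];
    const double* val = t->value[node].data();
    for (const auto& pf : path) {
      double* row = phi + (size_t)pf.first * C;
      const double w = (pf.second == 1) ? wplus : -wminus;
      for (int c = 0; c < C; ++c) row[c] += w * val[c];
    }
  }

  void walk(int node, int a, int b) {
    for (;;) {
      const int f = t->feature[node];
      if (f < 0) { leaf(node, a, b); return; }
      const bool xl = x[f] <= t->threshold[node];
      const bool zl = z[f] <= t->threshold[node];
      if (xl == zl) { node = xl ? t->left[node] : t->right[node]; continue; }
      if (state[f] == 1) { node = xl ? t->left[node] : t->right[node]; continue; }
      if (state[f] == 2) { node = zl ? t->left[node] : t->right[node]; continue; }
      state[f] = 1;
      path.emplace_back(f, 1);
      walk(xl ? t->left[node] : t->right[node], a + 1, b);
      path.back().second = 2;
      state[f] = 2;
      node = zl ? t->left[node] : t->right[node];
      ++b;
      // resume loop walking the z-branch; undo state when done
      walk(node, a, b);
      path.pop_back();
      state[f] = 0;
      return;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericMatrix Y, int n_trees, int mtry,
                int max_depth, int min_split, double seed) {
  const int n = X.nrow(), C = Y.ncol();
  std::vector<double> Yt((size_t)n * C); // transpose: column per sample
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c) Yt[(size_t)i * C + c] = Y(i, c);
  List trees(n_trees);
  for (int tnum = 0; tnum < n_trees; ++tnum) {
    Builder b(X, Yt, C, mtry, max_depth, min_split,
              (std::uint64_t)seed * 1000003ULL + (std::uint64_t)tnum);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = b.rng.below(n); // bootstrap
    b.build(idx, 0);
    const int nn = (int)b.tree.feature.size();
    NumericMatrix vals(nn, C);
    for (int i = 0; i < nn; ++i)
      if (b.tree.feature[i] < 0)
        for (int c = 0; c < C; ++c) vals(i, c) = b.tree.value[i][c];
    trees[tnum] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["threshold"] = NumericVector(b.tree.threshold.begin(), b.tree.threshold.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["value"] = vals);
    if (tnum % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int n_outputs) {
  const int n = X.nrow(), C = n_outputs, T = trees.size();
  NumericMatrix out(n, C);
  std::vector<double> xbuf(X.ncol());
  for (int tnum = 0; tnum < T; ++tnum) {
    Tree t = list_to_tree(trees[tnum]);
    for (int i = 0; i < n; ++i) {
      copy_row(X, i, xbuf);
      const std::vector<double>& v = tree_predict(t, xbuf.data());
      for (int c = 0; c < C; ++c) out(i, c) += v[c];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c) out(i, c) /= T;
  return out;
}

// Returns list(phi = n x d x C array, base = C vector). phi is averaged over
// trees and background rows; base is the mean model prediction over the
// background, so sum_f phi[i,f,] + base equals the model prediction at
// sample i exactly.
// [[Rcpp::export(name = ".rf_shap_cpp")]]
List rf_shap_cpp(List trees, NumericMatrix X, NumericMatrix B, int n_outputs) {
  const int n = X.nrow(), d = X.ncol(), C = n_outputs;
  const int T = trees.size(), m = B.nrow();
  if (m == 0) stop("background set is empty");
  ShapWeights W(d);
  std::vector<Tree> forest;
  forest.reserve(T);
  for (int tnum = 0; tnum < T; ++tnum)
    forest.push_back(list_to_tree(trees[tnum]));

  std::vector<std::vector<double>> zbuf(m, std::vector<double>(d));
  for (int z = 0; z < m; ++z) copy_row(B, z, zbuf[z]);

  NumericVector phi(Dimension(n, d, C));
  NumericVector base(C);
  for (const Tree& t : forest)
    for (int z = 0; z < m; ++z) {
      const std::vector<double>& v = tree_predict(t, zbuf[z].data());
      for (int c = 0; c < C; ++c) base[c] += v[c];
    }
  for (int c = 0; c < C; ++c) base[c] /= (double)T * m;

  ShapWalker wk(W, d, C);
  std::vector<double> slab((size_t)d * C), xbuf(d);
  for (int i = 0; i < n; ++i) {
    std::fill(slab.begin(), slab.end(), 0.0);
    copy_row(X, i, xbuf);
    wk.x = xbuf.data();
    wk.phi = slab.data();
    for (const Tree& t : forest) {
      wk.t = &t;
      for (int z = 0; z < m; ++z) {
        wk.z = zbuf[z].data();
        wk.walk(0, 0, 0);
      }
    }
    const double scale = 1.0 / ((double)T * m);
    double* ph = REAL(phi);
    for (int f = 0; f < d; ++f)
      for (int c = 0; c < C; ++c)
        ph[i + (size_t)n * (f + (size_t)d * c)] = slab[(size_t)f * C + c] * scale;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
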