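// Bootstrap ensemble of random-forest classifiers.
//
// Each ensemble member is a CART random forest (gini impurity, mtry features
// per node, per-tree bootstrap) trained on a bootstrap resample of the
// training set drawn with the member's own seed.  Trees are grown to purity
// (min_split = 2), matching the common library defaults for classification.
// All randomness comes from a splitmix64 stream seeded per member, so results
// are bit-reproducible across platforms and independent of R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int bounded(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct TreeBuf {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left;      // absolute node index
  std::vector<int> right;
  std::vector<int> pred;      // leaf class (0/1), majority for internal too
};

// Grow one tree on rows `idx` (indices into X) and accumulate impurity-based
// importance into `imp` (length p).  Returns nothing; nodes appended to buf.
void grow_tree(const double* X, int n_all, int p,
               const int* y, std::vector<int>& idx,
               int mtry, SplitMix64& rng,
               TreeBuf& buf, std::vector<double>& imp) {
  const int n_root = static_cast<int>(idx.size());
  struct Job { int lo, hi, slot; };
  std::vector<Job> stack;

  auto new_node = [&buf]() {
    buf.feat.push_back(-1); buf.thr.push_back(0.0);
    buf.left.push_back(-1); buf.right.push_back(-1);
    buf.pred.push_back(0);
    return static_cast<int>(buf.feat.size()) - 1;
  };

  std::vector<int> perm(p);
  std::vector<std::pair<double, int> > vals;
  vals.reserve(n_root);

  stack.push_back({0, n_root, new_node()});
  while (!stack.empty()) {
    Job job = stack.back(); stack.pop_back();
    const int n_node = job.hi - job.lo;
    int c1 = 0;
    for (int i = job.lo; i < job.hi; ++i) c1 += y[idx[i]];
    const int c0 = n_node - c1;
    buf.pred[job.slot] = (c1 > c0) ? 1 : 0;  // tie -> class 0
    if (c1 == 0 || c0 == 0 || n_node < 2) continue;  // pure / too small: leaf

    const double gini_node =
        1.0 - (double(c0) * c0 + double(c1) * c1) / (double(n_node) * n_node);

    // feature order: partial Fisher-Yates permutation
    for (int j = 0; j < p; ++j) perm[j] = j;
    for (int j = 0; j < p - 1; ++j) {
      int k = j + rng.bounded(p - j);
      std::swap(perm[j], perm[k]);
    }

    int best_f = -1, inspected = 0;
    double best_thr = 0.0, best_gain = 1e-12;
    for (int jj = 0; jj < p; ++jj) {
      if (inspected >= mtry && best_f >= 0) break;
      const int f = perm[jj];
      const double* col = X + static_cast<size_t>(f) * n_all;
      vals.clear();
      for (int i = job.lo; i < job.hi; ++i)
        vals.push_back(std::make_pair(col[idx[i]], y[idx[i]]));
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant here
      ++inspected;
      int nl = 0, c1l = 0;
      for (int i = 0; i + 1 < n_node; ++i) {
        ++nl; c1l += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nr = n_node - nl, c1r = c1 - c1l;
        const int c0l = nl - c1l, c0r = nr - c1r;
        const double gl = 1.0 - (double(c0l) * c0l + double(c1l) * c1l) / (double(nl) * nl);
        const double gr = 1.0 - (double(c0r) * c0r + double(c1r) * c1r) / (double(nr) * nr);
        const double gain = gini_node - (nl * gl + nr * gr) / n_node;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;  // no usable split: leaf with majority class

    imp[best_f] += best_gain * n_node / n_root;

    // partition idx[lo, hi) by the chosen split, preserving order
    std::vector<int> lhs, rhs;
    const double* col = X + static_cast<size_t>(best_f) * n_all;
    for (int i = job.lo; i < job.hi; ++i) {
      if (col[idx[i]] <= best_thr) lhs.push_back(idx[i]); else rhs.push_back(idx[i]);
    }
    std::copy(lhs.begin(), lhs.end(), idx.begin() + job.lo);
    std::copy(rhs.begin(), rhs.end(), idx.begin() + job.lo + lhs.size());

    const int slot_l = new_node();
    const int slot_r = new_node();
    buf.feat[job.slot] = best_f;
    buf.thr[job.slot] = best_thr;
    buf.left[job.slot] = slot_l;
    buf.right[job.slot] = slot_r;
    stack.push_back({job.lo, job.lo + static_cast<int>(lhs.size()), slot_l});
    stack.push_back({job.lo + static_cast<int>(lhs.size()), job.hi, slot_r});
  }
}

int predict_tree(const TreeBuf& buf, int root_offset_unused, int node,
                 const double* x) {
  (void)root_offset_unused;
  while (buf.feat[node] >= 0) {
    node = (x[buf.feat[node]] <= buf.thr[node]) ? buf.left[node] : buf.right[node];
  }
  return buf.pred[node];
}

}  // namespace

// Train an ensemble of `n_members` random forests with `n_trees` trees each.
// X: n x p training matrix (column-major via Rcpp), y: 0/1 labels,
// seeds: one 64-bit-ish seed per member (passed as doubles from R).
// Returns flat node arrays plus per-member normalised importance (rows sum 1).
// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_members, int n_trees,
                  int mtry, NumericVector seeds, bool member_bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  if (seeds.size() != n_members) stop("need one seed per member");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  TreeBuf buf;
  std::vector<int> tree_root;  // root node index of every tree
  tree_root.reserve(static_cast<size_t>(n_members) * n_trees);
  NumericMatrix importance(n_members, p);
  const double* Xp = REAL(X);
  std::vector<int> yv(y.begin(), y.end());

  std::vector<int> member_rows(n), tree_rows(n);
  std::vector<double> tree_imp(p), member_imp(p);

  for (int m = 0; m < n_members; ++m) {
    SplitMix64 rng(static_cast<uint64_t>(seeds[m]));
    // member-level bootstrap of the training set
    if (member_bootstrap) {
      for (int i = 0; i < n; ++i) member_rows[i] = rng.bounded(n);
    } else {
      for (int i = 0; i < n; ++i) member_rows[i] = i;
    }
    std::fill(member_imp.begin(), member_imp.end(), 0.0);
    for (int t = 0; t < n_trees; ++t) {
      // per-tree bootstrap within the member sample (standard RF bagging)
      for (int i = 0; i < n; ++i) tree_rows[i] = member_rows[rng.bounded(n)];
      std::fill(tree_imp.begin(), tree_imp.end(), 0.0);
      tree_root.push_back(static_cast<int>(buf.feat.size()));
      grow_tree(Xp, n, p, yv.data(), tree_rows, mtry, rng, buf, tree_imp);
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += tree_imp[j];
      if (s > 0) for (int j = 0; j < p; ++j) member_imp[j] += tree_imp[j] / s;
    }
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += member_imp[j];
    for (int j = 0; j < p; ++j)
      importance(m, j) = (s > 0) ? member_imp[j] / s : 1.0 / p;
  }

  return List::create(
      _["feat"] = IntegerVector(buf.feat.begin(), buf.feat.end()),
      _["thr"] = NumericVector(buf.thr.begin(), buf.thr.end()),
      _["left"] = IntegerVector(buf.left.begin(), buf.left.end()),
      _["right"] = IntegerVector(buf.right.begin(), buf.right.end()),
      _["pred"] = IntegerVector(buf.pred.begin(), buf.pred.end()),
      _["tree_root"] = IntegerVector(tree_root.begin(), tree_root.end()),
      _["n_members"] = n_members,
      _["n_trees"] = n_trees,
      _["importance"] = importance);
}

// Member-level class votes for new samples.  Each member votes the majority
// class of its trees (tie -> class 0).  Returns an n_samples x n_members 0/1
// integer matrix.
// [[Rcpp::export(name = ".rf_member_votes_cpp")]]
IntegerMatrix rf_member_votes_cpp(List model, NumericMatrix Xnew) {
  IntegerVector feat = model["feat"];
  NumericVector thr = model["thr"];
  IntegerVector left = model["left"];
  IntegerVector right = model["right"];
  IntegerVector pred = model["pred"];
  IntegerVector tree_root = model["tree_root"];
  const int n_members = model["n_members"];
  const int n_trees = model["n_trees"];
  const int n = Xnew.nrow(), p = Xnew.ncol();

  TreeBuf buf;
  buf.feat.assign(feat.begin(), feat.end());
  buf.thr.assign(thr.begin(), thr.end());
  buf.left.assign(left.begin(), left.end());
  buf.right.assign(right.begin(), right.end());
  buf.pred.assign(pred.begin(), pred.end());

  // sample-major copy of X so each sample's feature vector is contiguous
  std::vector<double> Xt(static_cast<size_t>(n) * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) Xt[static_cast<size_t>(i) * p + j] = Xnew(i, j);

  // tree-major traversal keeps one tree's nodes cache-hot across samples
  IntegerMatrix votes(n, n_members);
  std::vector<int> c1(n);
  for (int m = 0; m < n_members; ++m) {
    std::fill(c1.begin(), c1.end(), 0);
    for (int t = 0; t < n_trees; ++t) {
      const int root = tree_root[m * n_trees + t];
      for (int i = 0; i < n; ++i) {
        c1[i] += predict_tree(buf, 0, root, Xt.data() + static_cast<size_t>(i) * p);
      }
    }
    for (int i = 0; i < n; ++i) votes(i, m) = (2 * c1[i] > n_trees) ? 1 : 0;
  }
  return votes;
}
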