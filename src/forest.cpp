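// Minimal random-forest classifier (CART + bagging + feature subsampling),
// used for couple/sex classification from OTU counts. Gini splitting,
// bootstrap per tree, mtry features per node, majority vote. All randomness
// comes from R's RNG so set.seed() makes results reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;   // -1 for leaf
  double thr;    // go left when x <= thr
  int left, right;
  int pred;      // leaf class
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_classes, mtry, min_node;
  std::vector<Node> nodes;
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              int n_classes_, int mtry_, int min_node_)
      : X(X_), y(y_), n_classes(n_classes_), mtry(mtry_),
        min_node(min_node_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int majority(const std::vector<int>& idx) {
    std::vector<int> cnt(n_classes, 0);
    for (int i : idx) cnt[y[i]]++;
    return (int)(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
  }

  bool pure(const std::vector<int>& idx) {
    for (size_t k = 1; k < idx.size(); ++k)
      if (y[idx[k]] != y[idx[0]]) return false;
    return true;
  }

  int build(std::vector<int>& idx, int depth) {
    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, 0});
    if ((int)idx.size() < 2 * min_node || pure(idx) || depth > 48) {
      nodes[me].pred = majority(idx);
      return me;
    }
    // candidate features: partial Fisher-Yates over the feature pool
    int p = (int)feat_pool.size();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k)
      std::swap(feat_pool[k], feat_pool[k + rand_int(p - k)]);

    double best_score = -1.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int>> vals(idx.size());
    std::vector<int> left_cnt(n_classes), right_cnt(n_classes);

    std::vector<int> tot(n_classes, 0);
    for (int i : idx) tot[y[i]]++;
    double n = (double)idx.size();
    double gini_all = 0.0;
    for (int c = 0; c < n_classes; ++c) gini_all += (double)tot[c] * tot[c];
    gini_all = 1.0 - gini_all / (n * n);

    for (int k = 0; k < m; ++k) {
      int j = feat_pool[k];
      for (size_t t = 0; t < idx.size(); ++t)
        vals[t] = std::make_pair(X(idx[t], j), y[idx[t]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(left_cnt.begin(), left_cnt.end(), 0);
      for (int c = 0; c < n_classes; ++c) right_cnt[c] = tot[c];
      double sl = 0.0, sr = 0.0;
      for (int c = 0; c < n_classes; ++c)
        sr += (double)tot[c] * tot[c];
      for (size_t t = 0; t + 1 < vals.size(); ++t) {
        int c = vals[t].second;
        sl += 2.0 * left_cnt[c] + 1.0;
        sr -= 2.0 * right_cnt[c] - 1.0;
        left_cnt[c]++;
        right_cnt[c]--;
        if (vals[t].first == vals[t + 1].first) continue;
        double nl = (double)(t + 1), nr = n - nl;
        // impurity decrease ~ gini_all - (nl/n)(1 - sl/nl^2) - (nr/n)(1 - sr/nr^2)
        double score = sl / nl + sr / nr; // maximizing this == minimizing gini
        if (score > best_score) {
          best_score = score;
          best_feat = j;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_feat < 0) {
      nodes[me].pred = majority(idx);
      return me;
    }
    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) {
      nodes[me].pred = majority(idx);
      return me;
    }
    nodes[me].feature = best_feat;
    nodes[me].thr = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  int predict(const NumericMatrix& Xt, int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0)
      cur = (Xt(row, nodes[cur].feature) <= nodes[cur].thr)
                ? nodes[cur].left
                : nodes[cur].right;
    return nodes[cur].pred;
  }
};

} // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_cv_error")]]
List rf_cv_error(NumericMatrix X, IntegerVector y, int n_classes,
                 int n_folds, int n_repeats, int n_trees, int mtry,
                 int min_node) {
  int n = X.nrow();
  if (n != y.size()) stop("X rows must match y length");
  if (n_folds < 2) stop("n_folds must be >= 2");
  std::vector<std::vector<int>> by_class(n_classes);
  for (int i = 0; i < n; ++i) by_class[y[i]].push_back(i);
  std::vector<double> fold_err;
  fold_err.reserve((size_t)n_folds * n_repeats);
  long wrong_total = 0;
  std::vector<int> fold(n), train, test;
  std::vector<std::vector<int>> votes;
  for (int r = 0; r < n_repeats; ++r) {
    // stratified folds: shuffle within class, assign round-robin from a
    // random starting fold
    for (int c = 0; c < n_classes; ++c) {
      std::vector<int>& idx = by_class[c];
      for (int i = (int)idx.size() - 1; i > 0; --i)
        std::swap(idx[i], idx[rand_int(i + 1)]);
      int start = rand_int(n_folds);
      for (size_t t = 0; t < idx.size(); ++t)
        fold[idx[t]] = (start + (int)t) % n_folds;
    }
    for (int k = 0; k < n_folds; ++k) {
      train.clear();
      test.clear();
      for (int i = 0; i < n; ++i) (fold[i] == k ? test : train).push_back(i);
      if (test.empty() || train.empty()) continue;
      votes.assign(test.size(), std::vector<int>(n_classes, 0));
      for (int t = 0; t < n_trees; ++t) {
        std::vector<int> boot(train.size());
        for (size_t i = 0; i < train.size(); ++i)
          boot[i] = train[rand_int((int)train.size())];
        TreeBuilder tb(X, y, n_classes, mtry, min_node);
        tb.build(boot, 0);
        for (size_t t2 = 0; t2 < test.size(); ++t2)
          votes[t2][tb.predict(X, test[t2])]++;
      }
      int wrong = 0;
      for (size_t t2 = 0; t2 < test.size(); ++t2) {
        int best = 0;
        for (int c = 1; c < n_classes; ++c)
          if (votes[t2][c] > votes[t2][best]) best = c;
        if (best != y[test[t2]]) wrong++;
      }
      wrong_total += wrong;
      fold_err.push_back((double)wrong / (double)test.size());
    }
  }
  double err = (double)wrong_total / ((double)n * n_repeats);
  return List::create(Named("error") = err,
                      Named("fold_errors") = NumericVector(fold_err.begin(),
                                                           fold_err.end()));
}

//' @noRd
// [[Rcpp::export(name = ".rf_train_predict")]]
IntegerVector rf_train_predict(NumericMatrix X, IntegerVector y,
                               NumericMatrix Xtest, int n_classes,
                               int n_trees, int mtry, int min_node) {
  if (X.nrow() != y.size()) stop("X rows must match y length");
  if (X.ncol() != Xtest.ncol()) stop("train/test feature mismatch");
  if (n_trees < 1) stop("n_trees must be >= 1");
  int n = X.nrow(), nt = Xtest.nrow();
  std::vector<std::vector<int>> votes(nt, std::vector<int>(n_classes, 0));
  // RNG state is handled by the generated wrapper (RNGScope)
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rand_int(n);
    TreeBuilder tb(X, y, n_classes, mtry, min_node);
    tb.build(boot, 0);
    for (int r = 0; r < nt; ++r) votes[r][tb.predict(Xtest, r)]++;
  }
  IntegerVector out(nt);
  for (int r = 0; r < nt; ++r) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[r][c] > votes[r][best]) best = c;
    out[r] = best;
  }
  return out;
}
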