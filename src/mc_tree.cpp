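// Monte Carlo random-subspace scorer: per subspace, decision trees (CART,
// gini) are grown on bootstrap resamples; every feature accumulates
// (out-of-bag balanced accuracy of the tree) x (its share of the tree's
// total impurity decrease). The caller runs this twice -- once with the
// real labels and once with a permutation of them -- and uses the
// permuted run as the empirical null that calibrates the score cutoff.
//
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;        // split feature (local index), -1 for leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;         // leaf majority class
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p1 = double(n1) / n;
  return 2.0 * p1 * (1.0 - p1);
}

inline int runif_int(int n) {
  int k = int(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

class TreeBuilder {
public:
  TreeBuilder(const std::vector<const double*>& cols,
              const IntegerVector& y, int max_depth, int min_node)
    : cols_(cols), y_(y), max_depth_(max_depth), min_node_(min_node) {}

  std::vector<Node> nodes;
  std::vector<double> importance; // per local feature, impurity decrease

  void build(std::vector<int>& idx) {
    importance.assign(cols_.size(), 0.0);
    nodes.clear();
    n_root_ = int(idx.size());
    grow(idx, 0, int(idx.size()), 0);
  }

  int predict(int sample) const {
    int k = 0;
    while (nodes[k].feat >= 0)
      k = cols_[nodes[k].feat][sample] <= nodes[k].thr ? nodes[k].left
                                                       : nodes[k].right;
    return nodes[k].pred;
  }

private:
  const std::vector<const double*>& cols_;
  const IntegerVector& y_;
  int max_depth_, min_node_, n_root_ = 0;

  // Grow a node over idx[lo:hi); returns node id.
  int grow(std::vector<int>& idx, int lo, int hi, int depth) {
    int id = int(nodes.size());
    nodes.push_back(Node());
    int n = hi - lo, n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y_[idx[i]];
    nodes[id].pred = (2 * n1 > n) ? 1 : 0;
    double g = gini(n1, n);
    if (g <= 0.0 || n < min_node_ || depth >= max_depth_) return id;

    int best_f = -1, best_nl = 0;
    double best_dec = 0.0, best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (size_t f = 0; f < cols_.size(); ++f) {
      const double* col = cols_[f];
      for (int i = 0; i < n; ++i) {
        int s = idx[lo + i];
        vals[i] = {col[s], y_[s]};
      }
      std::sort(vals.begin(), vals.end());
      int nl1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        nl1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl, nr1 = n1 - nl1;
        double dec = g - (double(nl) / n) * gini(nl1, nl)
                       - (double(nr) / n) * gini(nr1, nr);
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_f = int(f);
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          best_nl = nl;
        }
      }
    }
    if (best_f < 0) return id;

    importance[best_f] += (double(n) / n_root_) * best_dec;
    // partition idx[lo:hi) stably around the threshold
    std::vector<int> l, r;
    l.reserve(best_nl);
    r.reserve(n - best_nl);
    const double* col = cols_[best_f];
    for (int i = lo; i < hi; ++i)
      (col[idx[i]] <= best_thr ? l : r).push_back(idx[i]);
    std::copy(l.begin(), l.end(), idx.begin() + lo);
    std::copy(r.begin(), r.end(), idx.begin() + lo + int(l.size()));
    nodes[id].feat = best_f;
    nodes[id].thr = best_thr;
    int mid = lo + int(l.size());
    nodes[id].left = grow(idx, lo, mid, depth + 1);
    nodes[id].right = grow(idx, mid, hi, depth + 1);
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".mc_subspace_score")]]
List mc_subspace_score(NumericMatrix X, IntegerVector y, List subspaces,
                       int trees_per_subspace, int max_depth, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector score(p);
  IntegerVector count(p);

  for (int s = 0; s < subspaces.size(); ++s) {
    IntegerVector sub = subspaces[s]; // 1-based locus indices
    const int m = sub.size();
    for (int j = 0; j < m; ++j) count[sub[j] - 1] += 1;

    std::vector<const double*> cols(m);
    for (int j = 0; j < m; ++j) cols[j] = &X(0, sub[j] - 1);

    TreeBuilder tb(cols, y, max_depth, min_node);
    std::vector<double> sub_score(m, 0.0);
    for (int t = 0; t < trees_per_subspace; ++t) {
      std::vector<int> bag(n);
      std::vector<char> inbag(n, 0);
      for (int i = 0; i < n; ++i) {
        bag[i] = runif_int(n);
        inbag[bag[i]] = 1;
      }
      tb.build(bag);

      // out-of-bag balanced accuracy over classes present out of bag
      int tot[2] = {0, 0}, hit[2] = {0, 0};
      for (int i = 0; i < n; ++i) {
        if (inbag[i]) continue;
        int c = y[i];
        tot[c] += 1;
        if (tb.predict(i) == c) hit[c] += 1;
      }
      double bal = 0.0;
      int ncls = 0;
      for (int c = 0; c < 2; ++c)
        if (tot[c] > 0) {
          bal += double(hit[c]) / tot[c];
          ncls += 1;
        }
      bal = ncls > 0 ? bal / ncls : 0.0;

      double tot_imp = 0.0;
      for (int f = 0; f < m; ++f) tot_imp += tb.importance[f];
      if (tot_imp <= 0.0) continue;
      for (int f = 0; f < m; ++f)
        sub_score[f] += bal * tb.importance[f] / tot_imp;
    }
    for (int j = 0; j < m; ++j)
      score[sub[j] - 1] += sub_score[j];
  }

  return List::create(_["score"] = score, _["count"] = count);
}
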