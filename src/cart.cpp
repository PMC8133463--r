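// Minimal CART regression-tree engine backing the boosted-tree and
// random-forest fitters. Greedy SSE-reduction splits with optional per-node
// feature subsampling (mtry). Trees are returned as flat arrays so fitted
// forests serialise as plain numeric matrices.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int var;        // -1 for leaf
  double split;   // threshold: go left if x <= split
  int left, right;
  double value;   // node mean of y
};

struct Task { int node; std::vector<int> rows; int depth; };

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, IntegerVector rows,
               int mtry, int max_depth, int min_node, int seed) {
  const int p = X.ncol();
  if (mtry <= 0 || mtry > p) mtry = p;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<Node> nodes;
  std::vector<Task> stack;

  std::vector<int> root(rows.begin(), rows.end());
  nodes.push_back({-1, 0.0, -1, -1, 0.0});
  stack.push_back({0, std::move(root), 0});

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  while (!stack.empty()) {
    Task task = std::move(stack.back());
    stack.pop_back();
    std::vector<int>& idx = task.rows;
    const int n = (int)idx.size();

    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    const double mean = sum / n;
    nodes[task.node].value = mean;
    const double sse = sum2 - sum * sum / n;

    bool can_split = n >= 2 * min_node && sse > 1e-12 &&
                     (max_depth <= 0 || task.depth < max_depth);
    if (!can_split) continue;

    // sample mtry candidate features without replacement
    std::shuffle(feats.begin(), feats.end(), rng);

    double best_gain = 0.0, best_split = 0.0;
    int best_var = -1;
    std::vector<int> ord(idx);

    for (int f = 0; f < mtry; ++f) {
      const int j = feats[f];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, j) < X(b, j);
      });
      double lsum = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        lsum += y[ord[i]];
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node) continue;
        if (nr < min_node) break;
        const double xl = X(ord[i], j), xr = X(ord[i + 1], j);
        if (xr <= xl) continue;  // tie, not a valid cut
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = j;
          best_split = 0.5 * (xl + xr);
        }
      }
    }

    if (best_var < 0) continue;

    std::vector<int> lrows, rrows;
    for (int i : idx) {
      if (X(i, best_var) <= best_split) lrows.push_back(i);
      else rrows.push_back(i);
    }
    if (lrows.empty() || rrows.empty()) continue;

    const int li = (int)nodes.size(), ri = li + 1;
    nodes[task.node].var = best_var;
    nodes[task.node].split = best_split;
    nodes[task.node].left = li;
    nodes[task.node].right = ri;
    nodes.push_back({-1, 0.0, -1, -1, 0.0});
    nodes.push_back({-1, 0.0, -1, -1, 0.0});
    stack.push_back({li, std::move(lrows), task.depth + 1});
    stack.push_back({ri, std::move(rrows), task.depth + 1});
  }

  const int m = (int)nodes.size();
  IntegerVector var(m), left(m), right(m);
  NumericVector split(m), value(m);
  for (int i = 0; i < m; ++i) {
    var[i] = nodes[i].var; split[i] = nodes[i].split;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["var"] = var, _["split"] = split,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export(name = ".cart_leaf")]]
IntegerVector cart_leaf(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector split = tree["split"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0) {
      node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
    }
    out[i] = node;
  }
  return out;
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  NumericVector value = tree["value"];
  IntegerVector leaf = cart_leaf(tree, X);
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = value[leaf[i]];
  return out;
}
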