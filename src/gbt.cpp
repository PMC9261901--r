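// Gradient-boosted decision trees with native missing-value handling.
//
// Exact greedy split search with the regularized gain
//   0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda))
// evaluated for both default directions of missing values; binary logistic
// objective. Deterministic: no subsampling, ties broken by the first
// (feature index, threshold) candidate reaching a strictly larger gain.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;        // -1 for leaf
  double threshold = 0.0;
  bool default_left = false;
  int left = -1, right = -1;
  double value = 0.0;      // leaf weight (already scaled by eta)
  double gain = 0.0;
  // split-search bookkeeping
  double G = 0.0, H = 0.0;
  int count = 0;
  double best_gain = 0.0;
  int best_feat = -1;
  double best_thr = 0.0;
  bool best_missing_left = false;
  int depth = 0;
};

static inline double score_term(double g, double h, double lambda) {
  return g * g / (h + lambda);
}

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, int nrounds,
                   double eta, int max_depth, double lambda,
                   double min_child_weight, double base_margin) {
  const int n = X.nrow(), p = X.ncol();
  // pre-sort non-missing row indices per feature (stable, once)
  std::vector<std::vector<int>> sorted(p);
  for (int j = 0; j < p; ++j) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i)
      if (!NumericMatrix::is_na(X(i, j))) idx.push_back(i);
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
    sorted[j] = std::move(idx);
  }

  std::vector<double> margin(n, base_margin), grad(n), hess(n);
  std::vector<int> node_of(n);
  List trees(nrounds);
  NumericVector total_gain(p), split_count(p);

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double prob = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = prob - y[i];
      hess[i] = prob * (1.0 - prob);
    }
    std::vector<Node> nodes(1);
    std::fill(node_of.begin(), node_of.end(), 0);
    std::vector<int> active = {0};
    for (int i = 0; i < n; ++i) {
      nodes[0].G += grad[i];
      nodes[0].H += hess[i];
      nodes[0].count++;
    }

    while (!active.empty()) {
      // reset best splits
      for (int nd : active) {
        nodes[nd].best_gain = 1e-10;  // required improvement
        nodes[nd].best_feat = -1;
      }
      // find best split per active node, feature by feature
      std::vector<double> Gnm(nodes.size()), Hnm(nodes.size());
      std::vector<double> gl(nodes.size()), hl(nodes.size());
      std::vector<double> lastv(nodes.size());
      std::vector<int> seen(nodes.size());
      for (int j = 0; j < p; ++j) {
        for (int nd : active) { Gnm[nd] = 0; Hnm[nd] = 0; }
        for (int i : sorted[j]) {
          int nd = node_of[i];
          Gnm[nd] += grad[i];
          Hnm[nd] += hess[i];
        }
        for (int nd : active) { gl[nd] = 0; hl[nd] = 0; seen[nd] = 0; }
        for (int i : sorted[j]) {
          int nd = node_of[i];
          Node &nod = nodes[nd];
          if (nod.count < 2 || nod.depth >= max_depth) continue;
          double x = X(i, j);
          if (seen[nd] > 0 && x > lastv[nd]) {
            double thr = 0.5 * (lastv[nd] + x);
            double Gmiss = nod.G - Gnm[nd], Hmiss = nod.H - Hnm[nd];
            // missing goes right
            {
              double GL = gl[nd], HL = hl[nd];
              double GR = nod.G - GL, HR = nod.H - HL;
              if (HL >= min_child_weight && HR >= min_child_weight) {
                double gn = 0.5 * (score_term(GL, HL, lambda) +
                                   score_term(GR, HR, lambda) -
                                   score_term(nod.G, nod.H, lambda));
                if (gn > nod.best_gain) {
                  nod.best_gain = gn;
                  nod.best_feat = j;
                  nod.best_thr = thr;
                  nod.best_missing_left = false;
                }
              }
            }
            // missing goes left
            {
              double GL = gl[nd] + Gmiss, HL = hl[nd] + Hmiss;
              double GR = nod.G - GL, HR = nod.H - HL;
              if (HL >= min_child_weight && HR >= min_child_weight) {
                double gn = 0.5 * (score_term(GL, HL, lambda) +
                                   score_term(GR, HR, lambda) -
                                   score_term(nod.G, nod.H, lambda));
                if (gn > nod.best_gain) {
                  nod.best_gain = gn;
                  nod.best_feat = j;
                  nod.best_thr = thr;
                  nod.best_missing_left = true;
                }
              }
            }
          }
          gl[nd] += grad[i];
          hl[nd] += hess[i];
          lastv[nd] = x;
          seen[nd]++;
        }
      }
      // materialize splits, reassign samples
      std::vector<int> next_active;
      for (int nd : active) {
        if (nodes[nd].best_feat < 0) continue;
        int li = (int)nodes.size(), ri = li + 1;
        nodes.push_back(Node());
        nodes.push_back(Node());
        Node &nod = nodes[nd];
        nod.feature = nod.best_feat;
        nod.threshold = nod.best_thr;
        nod.default_left = nod.best_missing_left;
        nod.left = li;
        nod.right = ri;
        nod.gain = nod.best_gain;
        nodes[li].depth = nodes[ri].depth = nod.depth + 1;
        total_gain[nod.feature] += nod.gain;
        split_count[nod.feature] += 1.0;
        next_active.push_back(li);
        next_active.push_back(ri);
      }
      if (next_active.empty()) break;
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        if (nodes[nd].feature < 0) continue;
        double x = X(i, nodes[nd].feature);
        bool go_left = NumericMatrix::is_na(x) ? nodes[nd].default_left
                                               : (x < nodes[nd].threshold);
        int child = go_left ? nodes[nd].left : nodes[nd].right;
        node_of[i] = child;
        nodes[child].G += grad[i];
        nodes[child].H += hess[i];
        nodes[child].count++;
      }
      active = std::move(next_active);
    }

    // leaf values and margin update
    for (auto &nod : nodes)
      if (nod.feature < 0)
        nod.value = -eta * nod.G / (nod.H + lambda);
    for (int i = 0; i < n; ++i) margin[i] += nodes[node_of[i]].value;

    NumericMatrix tm((int)nodes.size(), 7);
    colnames(tm) = CharacterVector::create("feature", "threshold",
                                           "default_left", "left", "right",
                                           "value", "gain");
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature;
      tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].default_left ? 1.0 : 0.0;
      tm(k, 3) = nodes[k].left;
      tm(k, 4) = nodes[k].right;
      tm(k, 5) = nodes[k].value;
      tm(k, 6) = nodes[k].gain;
    }
    trees[round] = tm;
  }

  return List::create(_["trees"] = trees,
                      _["total_gain"] = total_gain,
                      _["split_count"] = split_count,
                      _["base_margin"] = base_margin);
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List trees, NumericMatrix X,
                             double base_margin) {
  const int n = X.nrow();
  NumericVector margin(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (tm(nd, 0) >= 0) {
        int j = (int)tm(nd, 0);
        double x = X(i, j);
        bool go_left = NumericMatrix::is_na(x) ? (tm(nd, 2) > 0.5)
                                               : (x < tm(nd, 1));
        nd = (int)(go_left ? tm(nd, 3) : tm(nd, 4));
      }
      margin[i] += tm(nd, 5);
    }
  }
  return margin;
}
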