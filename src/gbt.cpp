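// Gradient-boosted regression trees with second-order (gradient/hessian)
// split gain, exact greedy splits over presorted feature columns, and
// total-gain feature importance. Squared-error and logistic objectives.
// Deterministic: no subsampling, ties resolved toward the first
// (feature, position) encountered in scan order.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                   int objective, // 0 = squared error, 1 = logistic
                   int nrounds, int max_depth, double eta, double lambda,
                   double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty design matrix");

  // Presort each feature once; node scans reuse the global order.
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::iota(order[j].begin(), order[j].end(), 0);
    const double* col = &X(0, j);
    std::stable_sort(order[j].begin(), order[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double wsum = 0.0, wy = 0.0;
  for (int i = 0; i < n; ++i) {
    wsum += w[i];
    wy += w[i] * y[i];
  }
  if (wsum <= 0) stop("weights sum to zero");
  double base;
  if (objective == 0) {
    base = wy / wsum;
  } else {
    double pbar = std::min(1.0 - 1e-6, std::max(1e-6, wy / wsum));
    base = std::log(pbar / (1.0 - pbar));
  }

  std::vector<double> f(n, base), g(n), h(n);
  std::vector<int> node_of(n);
  NumericVector importance(p);
  List trees(nrounds);
  const double min_gain = 1e-10;

  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) {
      if (objective == 0) {
        g[i] = w[i] * (f[i] - y[i]);
        h[i] = w[i];
      } else {
        double pr = 1.0 / (1.0 + std::exp(-f[i]));
        g[i] = w[i] * (pr - y[i]);
        h[i] = std::max(1e-16, w[i] * pr * (1.0 - pr));
      }
    }

    std::vector<int> feat_v(1, -1), left_v(1, -1), right_v(1, -1);
    std::vector<double> thr_v(1, 0.0), val_v(1, 0.0);
    std::fill(node_of.begin(), node_of.end(), 0);
    std::vector<int> level_nodes(1, 0);

    for (int depth = 0; depth < max_depth && !level_nodes.empty(); ++depth) {
      const int n_nodes = (int)feat_v.size();
      std::vector<double> G(n_nodes, 0.0), H(n_nodes, 0.0);
      for (int i = 0; i < n; ++i) {
        G[node_of[i]] += g[i];
        H[node_of[i]] += h[i];
      }
      std::vector<char> active(n_nodes, 0);
      for (size_t q = 0; q < level_nodes.size(); ++q) active[level_nodes[q]] = 1;

      std::vector<double> best_gain(n_nodes, min_gain), best_thr(n_nodes, 0.0);
      std::vector<int> best_feat(n_nodes, -1);
      std::vector<double> Gl(n_nodes), Hl(n_nodes), lastv(n_nodes);
      std::vector<char> seen(n_nodes);

      for (int j = 0; j < p; ++j) {
        for (size_t q = 0; q < level_nodes.size(); ++q) {
          int nd = level_nodes[q];
          Gl[nd] = 0.0;
          Hl[nd] = 0.0;
          seen[nd] = 0;
        }
        const double* col = &X(0, j);
        const std::vector<int>& ord = order[j];
        for (int k = 0; k < n; ++k) {
          int i = ord[k];
          int nd = node_of[i];
          if (!active[nd]) continue;
          double v = col[i];
          if (seen[nd] && v > lastv[nd]) {
            double gl = Gl[nd], hl = Hl[nd];
            double gr = G[nd] - gl, hr = H[nd] - hl;
            if (hl >= min_child_weight && hr >= min_child_weight) {
              double gain = gl * gl / (hl + lambda) + gr * gr / (hr + lambda) -
                            G[nd] * G[nd] / (H[nd] + lambda);
              if (gain > best_gain[nd]) {
                best_gain[nd] = gain;
                best_feat[nd] = j;
                best_thr[nd] = 0.5 * (lastv[nd] + v);
              }
            }
          }
          Gl[nd] += g[i];
          Hl[nd] += h[i];
          lastv[nd] = v;
          seen[nd] = 1;
        }
      }

      std::vector<int> next_level;
      for (size_t q = 0; q < level_nodes.size(); ++q) {
        int nd = level_nodes[q];
        if (best_feat[nd] >= 0) {
          int li = (int)feat_v.size();
          feat_v.push_back(-1); thr_v.push_back(0.0); left_v.push_back(-1);
          right_v.push_back(-1); val_v.push_back(0.0);
          int ri = (int)feat_v.size();
          feat_v.push_back(-1); thr_v.push_back(0.0); left_v.push_back(-1);
          right_v.push_back(-1); val_v.push_back(0.0);
          feat_v[nd] = best_feat[nd];
          thr_v[nd] = best_thr[nd];
          left_v[nd] = li;
          right_v[nd] = ri;
          importance[best_feat[nd]] += best_gain[nd];
          next_level.push_back(li);
          next_level.push_back(ri);
        } else {
          val_v[nd] = -eta * G[nd] / (H[nd] + lambda);
        }
      }
      for (int i = 0; i < n; ++i) {
        int nd = node_of[i];
        if (feat_v[nd] >= 0) {
          node_of[i] =
              (X(i, feat_v[nd]) < thr_v[nd]) ? left_v[nd] : right_v[nd];
        }
      }
      level_nodes.swap(next_level);
    }

    if (!level_nodes.empty()) { // depth limit reached: finalize leaves
      const int n_nodes = (int)feat_v.size();
      std::vector<double> G(n_nodes, 0.0), H(n_nodes, 0.0);
      for (int i = 0; i < n; ++i) {
        G[node_of[i]] += g[i];
        H[node_of[i]] += h[i];
      }
      for (size_t q = 0; q < level_nodes.size(); ++q) {
        int nd = level_nodes[q];
        val_v[nd] = -eta * G[nd] / (H[nd] + lambda);
      }
    }

    for (int i = 0; i < n; ++i) f[i] += val_v[node_of[i]];

    trees[r] = List::create(
        _["feature"] = IntegerVector(feat_v.begin(), feat_v.end()),
        _["threshold"] = NumericVector(thr_v.begin(), thr_v.end()),
        _["left"] = IntegerVector(left_v.begin(), left_v.end()),
        _["right"] = IntegerVector(right_v.begin(), right_v.end()),
        _["value"] = NumericVector(val_v.begin(), val_v.end()));
  }

  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["gain"] = importance, _["objective"] = objective);
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double base = as<double>(model["base_score"]);
  List trees = model["trees"];
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0) {
        nd = (X(i, feature[nd]) < threshold[nd]) ? left[nd] : right[nd];
      }
      out[i] += value[nd];
    }
  }
  return out;
}
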