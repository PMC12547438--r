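#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Regression trees grown by greedy squared-error reduction, used as the
// base learner of the boosting ensemble. A fitted tree is a node matrix:
//   col 0: split feature (0-based; -1 for a leaf)
//   col 1: split threshold (midpoint between consecutive distinct values)
//   col 2: left child row  (-1 for a leaf)   [x <= threshold]
//   col 3: right child row (-1 for a leaf)   [x >  threshold]
//   col 4: node value (mean of in-node targets; the prediction at leaves)
//
// Split search: candidates are midpoints between consecutive sorted unique
// feature values with both sides holding >= minobs rows; ties in SSE
// reduction are broken toward the lowest feature index, then the lowest
// threshold (features scanned in column order, thresholds ascending, and a
// new best accepted only on strict improvement).

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& y;
  int minobs;
  std::vector<double> feat, thr, val;
  std::vector<int> left, right;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& y_, int minobs_)
    : X(X_), y(y_), minobs(minobs_) {}

  int build(std::vector<int>& rows, int depth_left) {
    const int id = static_cast<int>(feat.size());
    feat.push_back(-1.0);
    thr.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);

    const int n = static_cast<int>(rows.size());
    double s = 0.0, ymin = y[rows[0]], ymax = y[rows[0]];
    for (int i = 0; i < n; ++i) {
      const double yi = y[rows[i]];
      s += yi;
      if (yi < ymin) ymin = yi;
      if (yi > ymax) ymax = yi;
    }
    val.push_back(s / n);

    // constant targets admit no SSE-reducing split
    if (depth_left <= 0 || n < 2 * minobs || ymin == ymax) return id;

    const int p = X.ncol();
    const double base = s * s / n;
    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;

    std::vector<std::pair<double, double> > xy(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i)
        xy[i] = std::make_pair(X(rows[i], j), y[rows[i]]);
      std::sort(xy.begin(), xy.end());
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;  // not a value boundary
        const int nl = i + 1, nr = n - nl;
        if (nl < minobs || nr < minobs) continue;
        const double sr = s - sl;
        const double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = j;
          best_thr = xy[i].first + (xy[i + 1].first - xy[i].first) / 2.0;
        }
      }
    }

    if (best_f < 0) return id;  // no legal, improving split: stay a leaf

    std::vector<int> lrows, rrows;
    lrows.reserve(n);
    rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_f) <= best_thr) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    feat[id] = best_f;
    thr[id] = best_thr;
    left[id] = build(lrows, depth_left - 1);
    right[id] = build(rrows, depth_left - 1);
    return id;
  }

  NumericMatrix to_matrix() const {
    const int m = static_cast<int>(feat.size());
    NumericMatrix out(m, 5);
    for (int i = 0; i < m; ++i) {
      out(i, 0) = feat[i];
      out(i, 1) = thr[i];
      out(i, 2) = left[i];
      out(i, 3) = right[i];
      out(i, 4) = val[i];
    }
    return out;
  }
};

static double predict_row(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0.0) {
    const int f = static_cast<int>(tree(node, 0));
    node = (X(row, f) <= tree(node, 1))
      ? static_cast<int>(tree(node, 2))
      : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

// [[Rcpp::export]]
NumericMatrix fit_tree_cpp(NumericMatrix X, NumericVector y, int depth, int minobs) {
  const int n = X.nrow();
  if (n < 1 || y.size() != n) stop("features and targets must have matching, positive length");
  std::vector<double> yv(y.begin(), y.end());
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  TreeBuilder tb(X, yv, minobs);
  tb.build(rows, depth);
  return tb.to_matrix();
}

// [[Rcpp::export]]
NumericVector tree_predict_cpp(NumericMatrix tree, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = predict_row(tree, X, i);
  return out;
}

// minimal-standard Lehmer generator (Park-Miller, modulus 2^31 - 1);
// drives per-tree row subsampling so each bag is a pure function of its
// derived seed, independent of every other tree
struct Lehmer {
  unsigned long long state;
  explicit Lehmer(int seed) : state(seed <= 0 ? 1u : (unsigned) seed) {}
  unsigned long long next() {
    state = (state * 48271ULL) % 2147483647ULL;
    return state;
  }
  // uniform integer in [0, k)
  int below(int k) { return static_cast<int>(next() % (unsigned long long) k); }
};

// Stochastic gradient boosting with squared-error loss. Tree m is fitted to
// the current residuals of n_bag rows drawn without replacement (partial
// Fisher-Yates under a Lehmer generator seeded with tree_seeds[m]); then the
// fitted values of ALL rows are shifted by shrinkage * tree. Nodes of all
// trees are returned flat (one matrix) with per-tree start offsets, to avoid
// allocating hundreds of small R objects per fit.
// [[Rcpp::export]]
List boost_fit_cpp(NumericMatrix X, NumericVector y, int n_bag,
                   int depth, int minobs, double shrinkage,
                   IntegerVector tree_seeds) {
  const int n = X.nrow();
  const int ntrees = tree_seeds.size();
  double baseline = 0.0;
  for (int i = 0; i < n; ++i) baseline += y[i];
  baseline /= n;

  NumericVector fitted(n, baseline);
  std::vector<double> resid(n);
  std::vector<double> feat_all, thr_all, val_all;
  std::vector<int> left_all, right_all, offsets(ntrees + 1, 0);
  std::vector<int> idx(n), rows(n_bag);

  for (int m = 0; m < ntrees; ++m) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fitted[i];
    // draw the bag: first n_bag entries of a seeded partial shuffle
    Lehmer rng(tree_seeds[m]);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < n_bag; ++i) {
      const int j = i + rng.below(n - i);
      std::swap(idx[i], idx[j]);
      rows[i] = idx[i];
    }
    TreeBuilder tb(X, resid, minobs);
    std::vector<int> bag(rows);
    tb.build(bag, depth);

    const int base = static_cast<int>(feat_all.size());
    const int nn = static_cast<int>(tb.feat.size());
    for (int k = 0; k < nn; ++k) {
      feat_all.push_back(tb.feat[k]);
      thr_all.push_back(tb.thr[k]);
      val_all.push_back(tb.val[k]);
      left_all.push_back(tb.left[k] < 0 ? -1 : tb.left[k] + base);
      right_all.push_back(tb.right[k] < 0 ? -1 : tb.right[k] + base);
    }
    offsets[m + 1] = base + nn;

    // update fitted values of every row with the new tree
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tb.feat[node] >= 0.0) {
        const int f = static_cast<int>(tb.feat[node]);
        node = (X(i, f) <= tb.thr[node]) ? tb.left[node] : tb.right[node];
      }
      fitted[i] += shrinkage * tb.val[node];
    }
  }

  const int total = static_cast<int>(feat_all.size());
  NumericMatrix nodes(total, 5);
  for (int k = 0; k < total; ++k) {
    nodes(k, 0) = feat_all[k];
    nodes(k, 1) = thr_all[k];
    nodes(k, 2) = left_all[k];
    nodes(k, 3) = right_all[k];
    nodes(k, 4) = val_all[k];
  }
  return List::create(_["baseline"] = baseline,
                      _["nodes"] = nodes,
                      _["offsets"] = IntegerVector(offsets.begin(),
                                                   offsets.end()),
                      _["fitted"] = fitted);
}

// Specialized leave-one-out driver for depth-1 (stump) ensembles: for each
// left-out case j, boosts stumps on the remaining rows and records the
// prediction for j. Split search scans per-feature presorted row orders
// instead of re-sorting every bag, which is what makes replicated LOO
// affordable. Given the same per-tree seeds it reproduces the models of
// boost_fit_cpp at depth 1 (up to floating-point summation order).
// tree_seeds is ntrees x n: column j seeds the trees of the fit without j.
// [[Rcpp::export]]
NumericVector loo_boost_stump_cpp(NumericMatrix X, NumericVector y,
                                  int minobs, double shrinkage,
                                  double bag_fraction,
                                  IntegerMatrix tree_seeds) {
  const int n = X.nrow(), p = X.ncol();
  const int ntrees = tree_seeds.nrow();

  // presort rows once per feature (ascending value)
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& o = order[f];
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&X, f](int a, int b) { return X(a, f) < X(b, f); });
  }

  double sum_y = 0.0;
  for (int i = 0; i < n; ++i) sum_y += y[i];

  NumericVector out(n);
  std::vector<double> fitted(n), resid(n);
  std::vector<int> subidx(n - 1), idx(n - 1);
  std::vector<char> inbag(n);

  for (int j = 0; j < n; ++j) {
    const int n_sub = n - 1;
    int n_bag = static_cast<int>(std::ceil(bag_fraction * n_sub));
    if (n_bag < 1) n_bag = 1;
    const double baseline = (sum_y - y[j]) / n_sub;
    std::fill(fitted.begin(), fitted.end(), baseline);
    int k = 0;
    for (int i = 0; i < n; ++i) if (i != j) subidx[k++] = i;

    for (int m = 0; m < ntrees; ++m) {
      for (int i = 0; i < n; ++i) if (i != j) resid[i] = y[i] - fitted[i];

      Lehmer rng(tree_seeds(m, j));
      for (int i = 0; i < n_sub; ++i) idx[i] = i;
      std::fill(inbag.begin(), inbag.end(), 0);
      for (int i = 0; i < n_bag; ++i) {
        const int t = i + rng.below(n_sub - i);
        std::swap(idx[i], idx[t]);
        inbag[subidx[idx[i]]] = 1;
      }

      double s = 0.0, rmin = 0.0, rmax = 0.0;
      bool first = true;
      for (int i = 0; i < n; ++i) {
        if (!inbag[i]) continue;
        const double ri = resid[i];
        s += ri;
        if (first) { rmin = rmax = ri; first = false; }
        else { if (ri < rmin) rmin = ri; if (ri > rmax) rmax = ri; }
      }

      double lv = 0.0, rv = 0.0, thr = 0.0;
      int best_f = -1;
      if (rmin < rmax && n_bag >= 2 * minobs) {
        const double base = s * s / n_bag;
        double best_gain = 0.0, best_sl = 0.0;
        int best_nl = 0;
        for (int f = 0; f < p; ++f) {
          const std::vector<int>& o = order[f];
          double sl = 0.0, prev_x = 0.0;
          int nl = 0;
          for (int oi = 0; oi < n; ++oi) {
            const int row = o[oi];
            if (!inbag[row]) continue;
            const double xv = X(row, f);
            if (nl > 0 && xv > prev_x && nl >= minobs &&
                n_bag - nl >= minobs) {
              const double sr = s - sl;
              const double gain =
                sl * sl / nl + sr * sr / (n_bag - nl) - base;
              if (gain > best_gain) {
                best_gain = gain;
                best_f = f;
                thr = prev_x + (xv - prev_x) / 2.0;
                best_sl = sl;
                best_nl = nl;
              }
            }
            sl += resid[row];
            ++nl;
            prev_x = xv;
          }
        }
        if (best_f >= 0) {
          lv = best_sl / best_nl;
          rv = (s - best_sl) / (n_bag - best_nl);
        }
      }
      if (best_f < 0) {  // degenerate tree: single leaf of the bag mean
        const double leaf = s / n_bag;
        for (int i = 0; i < n; ++i) fitted[i] += shrinkage * leaf;
      } else {
        for (int i = 0; i < n; ++i)
          fitted[i] += shrinkage * (X(i, best_f) <= thr ? lv : rv);
      }
    }
    out[j] = fitted[j];
  }
  return out;
}

// Evaluate baseline + shrinkage * sum of trees; offsets has length
// ntrees + 1 and gives each tree's root row in the flat node matrix.
// [[Rcpp::export]]
NumericVector boost_predict_cpp(NumericMatrix nodes, IntegerVector offsets,
                                double baseline, double shrinkage,
                                NumericMatrix X) {
  const int n = X.nrow();
  const int ntrees = offsets.size() - 1;
  NumericVector out(n, baseline);
  for (int m = 0; m < ntrees; ++m) {
    const int root = offsets[m];
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (nodes(node, 0) >= 0.0) {
        const int f = static_cast<int>(nodes(node, 0));
        node = (X(i, f) <= nodes(node, 1))
          ? static_cast<int>(nodes(node, 2))
          : static_cast<int>(nodes(node, 3));
      }
      out[i] += shrinkage * nodes(node, 4);
    }
  }
  return out;
}
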