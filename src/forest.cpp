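#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimal CART random forest for binary classification, built for the
// shadow-variable selection wrapper: bootstrap + Gini splits + out-of-bag
// (OOB) permutation importance.  Uses R's RNG so results are reproducible
// under set.seed().

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node ids
  std::vector<int> pred;        // leaf class (0/1)
};

int rand_int(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double gini(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p, mtry, min_node;
  Tree tree;
  std::vector<double>& gini_imp; // accumulated impurity decrease
  std::vector<int> used;         // features used by this tree (unique)
  std::vector<char> used_mark;
  double n_total;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, std::vector<double>& gini_imp_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_node(min_node_),
        gini_imp(gini_imp_), used_mark(X_.ncol(), 0), n_total(0) {}

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);
    return (int)tree.feature.size() - 1;
  }

  // rows may contain duplicates (bootstrap multiplicity)
  int build(std::vector<int>& rows) {
    int node = new_node();
    int n0 = 0, n1 = 0;
    for (int r : rows) (y[r] == 0 ? n0 : n1)++;
    int n = n0 + n1;
    tree.pred[node] = (n1 > n0) ? 1 : 0;
    if (n0 == 0 || n1 == 0 || n < 2 * min_node) return node;

    double parent_imp = gini(n0, n1);
    // sample mtry candidate features without replacement
    static thread_local std::vector<int> cand;
    cand.resize(p);
    for (int i = 0; i < p; ++i) cand[i] = i;
    int m = std::min(mtry, p);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(n);
    for (int k = 0; k < m; ++k) {
      int swap_at = k + rand_int(p - k);
      std::swap(cand[k], cand[swap_at]);
      int f = cand[k];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(rows[i], f), y[rows[i]]);
      std::sort(vals.begin(), vals.end());
      double l0 = 0, l1 = 0, r0 = n0, r1 = n1;
      for (int i = 0; i < n - 1; ++i) {
        (vals[i].second == 0 ? l0 : l1)++;
        (vals[i].second == 0 ? r0 : r1)--;
        if (vals[i + 1].first <= vals[i].first) continue; // tie, no cut here
        double nl = l0 + l1, nr = r0 + r1;
        double child = (nl * gini(l0, l1) + nr * gini(r0, r1)) / n;
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> lrows, rrows;
    lrows.reserve(n);
    rrows.reserve(n);
    for (int r : rows)
      (X(r, best_f) <= best_thr ? lrows : rrows).push_back(r);
    if (lrows.empty() || rrows.empty()) return node;

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    gini_imp[best_f] += best_gain * n / n_total;
    if (!used_mark[best_f]) {
      used_mark[best_f] = 1;
      used.push_back(best_f);
    }
    int l = build(lrows);
    int r = build(rrows);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

int predict_row(const Tree& t, const NumericMatrix& X, int row, int perm_f,
                double perm_val) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    double v = (f == perm_f) ? perm_val : X(row, f);
    node = (v <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            int min_node, bool perm_importance, bool keep_forest) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> gini_imp(p, 0.0), imp_sum(p, 0.0), imp_sumsq(p, 0.0);
  std::vector<int> oob_votes1(n, 0), oob_cnt(n, 0);
  List forest(keep_forest ? ntree : 0);
  std::vector<int> inbag(n), rows, oob;
  std::vector<double> permval;
  std::vector<int> perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    rows.clear();
    for (int i = 0; i < n; ++i) {
      int r = rand_int(n);
      inbag[r]++;
      rows.push_back(r);
    }
    Builder bl(X, y, mtry, min_node, gini_imp);
    bl.n_total = (double)n;
    bl.build(rows);
    const Tree& tr = bl.tree;

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);

    if (!oob.empty()) {
      int correct = 0;
      for (int i : oob) {
        int pr = predict_row(tr, X, i, -1, 0.0);
        oob_votes1[i] += pr;
        oob_cnt[i]++;
        if (pr == y[i]) correct++;
      }
      if (perm_importance) {
        int m = (int)oob.size();
        perm.resize(m);
        for (int i = 0; i < m; ++i) perm[i] = i;
        for (int f : bl.used) {
          // fresh permutation of the OOB values of feature f
          for (int i = m - 1; i > 0; --i)
            std::swap(perm[i], perm[rand_int(i + 1)]);
          int cperm = 0;
          for (int i = 0; i < m; ++i) {
            double v = X(oob[perm[i]], f);
            if (predict_row(tr, X, oob[i], f, v) == y[oob[i]]) cperm++;
          }
          double diff = (double)(correct - cperm) / m;
          imp_sum[f] += diff;
          imp_sumsq[f] += diff * diff;
        }
      }
    }

    if (keep_forest) {
      int nn = (int)tr.feature.size();
      NumericMatrix tm(nn, 5);
      for (int i = 0; i < nn; ++i) {
        tm(i, 0) = tr.feature[i];
        tm(i, 1) = tr.threshold[i];
        tm(i, 2) = tr.left[i];
        tm(i, 3) = tr.right[i];
        tm(i, 4) = tr.pred[i];
      }
      forest[t] = tm;
    }
  }

  NumericVector imp_mean(p), imp_sd(p), gini_out(p);
  for (int f = 0; f < p; ++f) {
    double mu = imp_sum[f] / ntree;
    imp_mean[f] = mu;
    double var = (ntree > 1)
        ? (imp_sumsq[f] - ntree * mu * mu) / (ntree - 1)
        : 0.0;
    imp_sd[f] = var > 0 ? std::sqrt(var) : 0.0;
    gini_out[f] = gini_imp[f];
  }
  int oob_wrong = 0, oob_n = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] == 0) continue;
    oob_n++;
    int pred = (2 * oob_votes1[i] > oob_cnt[i]) ? 1 : 0;
    if (pred != y[i]) oob_wrong++;
  }
  return List::create(
      _["imp_mean"] = imp_mean, _["imp_sd"] = imp_sd, _["gini"] = gini_out,
      _["oob_error"] = oob_n > 0 ? (double)oob_wrong / oob_n : NA_REAL,
      _["forest"] = forest, _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".rf_predict_votes")]]
NumericVector rf_predict_votes(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector votes(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      votes[i] += tm(node, 4);
    }
  }
  return votes / (double)ntree;
}
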