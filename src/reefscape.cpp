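#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ----------------------------------------------------------------------------
// Stochastic gradient boosting for Bernoulli response with depth-limited
// regression trees fit to gradient residuals. Trees are stored flattened in
// growing arrays shared by all trees of one fit; `offsets` marks each root.
// ----------------------------------------------------------------------------

struct Forest {
  std::vector<int> var;        // split feature (0-based), -1 for leaf
  std::vector<double> split;   // threshold (x <= split goes left)
  std::vector<double> value;   // Newton leaf value (unshrunk)
  std::vector<int> left, right; // absolute node indices, -1 for leaf
  std::vector<int> offsets;    // root index of each tree
};

// best split on one node: exhaustive over sorted unique values, midpoint
// thresholds, first-best tie-breaking in column order
struct SplitInfo {
  int feat = -1;
  double thresh = 0.0;
  double gain = 0.0;
};

static SplitInfo find_split(const NumericMatrix& X,
                            const std::vector<double>& z,
                            const std::vector<int>& idx,
                            int min_leaf) {
  SplitInfo best;
  const int n = (int)idx.size();
  if (n < 2 * min_leaf) return best;
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += z[idx[i]];
  const double base = S * S / n;
  const int p = X.ncol();
  std::vector<std::pair<double, double>> xv(n); // (x, z)
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      xv[i].first = X(idx[i], j);
      xv[i].second = z[idx[i]];
    }
    std::sort(xv.begin(), xv.end());
    double SL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      SL += xv[i].second;
      if (xv[i].first == xv[i + 1].first) continue; // not between distinct values
      const int nL = i + 1, nR = n - nL;
      if (nL < min_leaf || nR < min_leaf) continue;
      const double SR = S - SL;
      const double gain = SL * SL / nL + SR * SR / nR - base;
      if (gain > best.gain + 1e-12) { // strict: earlier column/threshold wins ties
        best.gain = gain;
        best.feat = j;
        best.thresh = 0.5 * (xv[i].first + xv[i + 1].first);
      }
    }
  }
  return best;
}

static double newton_value(const std::vector<double>& z,
                           const std::vector<double>& h,
                           const std::vector<int>& idx) {
  double num = 0.0, den = 0.0;
  for (int i : idx) { num += z[i]; den += h[i]; }
  if (den < 1e-12) return 0.0;
  return num / den;
}

// recursive grower; returns absolute node index
static int grow_node(Forest& fo, const NumericMatrix& X,
                     const std::vector<double>& z, const std::vector<double>& h,
                     std::vector<int>& idx, int depth, int max_depth,
                     int min_leaf, std::vector<double>& var_gain) {
  const int me = (int)fo.var.size();
  fo.var.push_back(-1);
  fo.split.push_back(0.0);
  fo.value.push_back(newton_value(z, h, idx));
  fo.left.push_back(-1);
  fo.right.push_back(-1);
  if (depth >= max_depth) return me;
  SplitInfo s = find_split(X, z, idx, min_leaf);
  if (s.feat < 0 || s.gain <= 0.0) return me;
  std::vector<int> li, ri;
  li.reserve(idx.size()); ri.reserve(idx.size());
  for (int i : idx) {
    if (X(i, s.feat) <= s.thresh) li.push_back(i); else ri.push_back(i);
  }
  fo.var[me] = s.feat;
  fo.split[me] = s.thresh;
  var_gain[s.feat] += s.gain;
  fo.left[me] = grow_node(fo, X, z, h, li, depth + 1, max_depth, min_leaf, var_gain);
  fo.right[me] = grow_node(fo, X, z, h, ri, depth + 1, max_depth, min_leaf, var_gain);
  return me;
}

static double tree_value_at(const Forest& fo, int root,
                            const NumericMatrix& X, int row) {
  int node = root;
  while (fo.var[node] >= 0) {
    node = (X(row, fo.var[node]) <= fo.split[node]) ? fo.left[node]
                                                    : fo.right[node];
  }
  return fo.value[node];
}

static inline double bern_dev(const double y, const double F) {
  // -2 (y F - log(1 + e^F)), computed stably
  double l1p = (F > 0) ? F + std::log1p(std::exp(-F)) : std::log1p(std::exp(F));
  return -2.0 * (y * F - l1p);
}

// [[Rcpp::export]]
List cpp_boost(NumericMatrix X, NumericVector y, double intercept,
               double lr, int max_depth, int min_leaf, double bag_fraction,
               int n_trees, NumericMatrix Xval, NumericVector yval,
               int stride) {
  const int n = X.nrow(), p = X.ncol();
  const int nval = Xval.nrow();
  const int m = std::max(1, (int)std::floor(bag_fraction * n + 1e-9));
  Forest fo;
  std::vector<double> F(n, intercept), Fval(nval, intercept);
  std::vector<double> z(n), h(n);
  NumericMatrix improvements(n_trees, p);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  const int n_strides = n_trees / stride;
  NumericVector train_dev(n_strides), val_dev(n_strides);
  NumericMatrix valF(nval, n_strides);
  IntegerVector stride_trees(n_strides);

  RNGScope scope;
  for (int t = 0; t < n_trees; ++t) {
    // gradient and hessian at current fit
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      z[i] = y[i] - pr;
      h[i] = std::max(pr * (1.0 - pr), 1e-12);
    }
    // bag: seeded sample without replacement (partial Fisher-Yates on R RNG)
    std::vector<int> bag(m);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(perm[i], perm[j]);
      bag[i] = perm[i];
    }
    std::vector<double> vg(p, 0.0);
    fo.offsets.push_back((int)fo.var.size());
    int root = grow_node(fo, X, z, h, bag, 0, max_depth, min_leaf, vg);
    for (int j = 0; j < p; ++j) improvements(t, j) = vg[j];
    for (int i = 0; i < n; ++i) F[i] += lr * tree_value_at(fo, root, X, i);
    for (int i = 0; i < nval; ++i)
      Fval[i] += lr * tree_value_at(fo, root, Xval, i);

    if ((t + 1) % stride == 0) {
      int s = (t + 1) / stride - 1;
      double td = 0.0, vd = 0.0;
      for (int i = 0; i < n; ++i) td += bern_dev(y[i], F[i]);
      train_dev[s] = td / n;
      if (nval > 0) {
        for (int i = 0; i < nval; ++i) vd += bern_dev(yval[i], Fval[i]);
        val_dev[s] = vd / nval;
        for (int i = 0; i < nval; ++i) valF(i, s) = Fval[i];
      }
      stride_trees[s] = t + 1;
    }
  }
  fo.offsets.push_back((int)fo.var.size());
  return List::create(
    _["var"] = wrap(fo.var), _["split"] = wrap(fo.split),
    _["value"] = wrap(fo.value), _["left"] = wrap(fo.left),
    _["right"] = wrap(fo.right), _["offsets"] = wrap(fo.offsets),
    _["improvements"] = improvements,
    _["train_dev"] = train_dev, _["val_dev"] = val_dev,
    _["val_F"] = valF, _["stride_trees"] = stride_trees,
    _["final_F"] = wrap(F));
}

// sum of (unshrunk) leaf values of the first n_use trees at each row of X
// [[Rcpp::export]]
NumericVector cpp_forest_sum(IntegerVector var, NumericVector split,
                             NumericVector value, IntegerVector left,
                             IntegerVector right, IntegerVector offsets,
                             int n_use, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < n_use; ++t) {
    const int root = offsets[t];
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (var[node] >= 0)
        node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out;
}

// ----------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher two-pass
// lower-envelope algorithm). Input: logical mask; output: squared distance in
// cell units to the nearest TRUE cell (0 inside the mask). Exact
// center-to-center distances.
// ----------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  // intersection of parabolas rooted at q and p; -INF pops p, +INF never wins
  auto intersect = [&](int q, int p) -> double {
    if (f[p] == INF) return -INF;
    return ((f[q] + q * (double)q) - (f[p] + p * (double)p)) /
           (2.0 * q - 2.0 * p);
  };
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue; // an empty site never forms a lower envelope
    double s = 0.0;
    while (k >= 0) {
      s = intersect(q, v[k]);
      if (s <= zb[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF;
    } else {
      ++k;
      v[k] = q; zb[k] = s; zb[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), dd(std::max(nr, nc));
  // pass 1: along columns
  for (int j = 0; j < nc; ++j) {
    f.resize(nr); dd.resize(nr);
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, dd);
    for (int i = 0; i < nr; ++i) d(i, j) = dd[i];
  }
  // pass 2: along rows
  for (int i = 0; i < nr; ++i) {
    f.resize(nc); dd.resize(nc);
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, dd);
    for (int j = 0; j < nc; ++j) d(i, j) = dd[j];
  }
  return d;
}
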