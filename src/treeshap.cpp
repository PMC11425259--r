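#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact interventional Shapley attribution for binary decision-tree
// ensembles, averaged over a background set.
//
// For one explained sample x, one background row b and one tree, the
// model restricted to a feature coalition S is f(x_S, b_~S). Each leaf
// is reachable only if the features where x and b disagree on the path
// take prescribed sides: a set D must come from x (subset of S) and a
// set C from b (disjoint from S). The Shapley value of such an
// AND-of-literals game has the closed form
//   phi_i = v * (d-1)! c! / (d+c)!    for i in D,
//   phi_i = -v * d! (c-1)! / (d+c)!   for i in C,
// with d = |D|, c = |C| and v the leaf value; features off the path get
// zero. Attributions are summed over leaves and averaged over trees and
// background rows.

namespace {

struct TreeView {
  const double *left, *right, *var, *split, *value;
  int n;
};

struct Walker {
  const TreeView &tree;
  const double *x, *b;
  std::vector<int> state;           // 0 free, 1 must-from-x, 2 must-from-b
  std::vector<int> touched;         // features with non-zero state
  int d = 0, c = 0;
  double *phi;                      // length p accumulator
  const std::vector<double> &fact;

  Walker(const TreeView &t, const double *x_, const double *b_, int p,
         double *phi_, const std::vector<double> &fact_)
      : tree(t), x(x_), b(b_), state(p, 0), phi(phi_), fact(fact_) {}

  void walk(int node) {
    int f = (int)tree.var[node - 1];  // 1-based feature, 0 = leaf
    if (f == 0) {
      double v = tree.value[node - 1];
      if ((d == 0 && c == 0) || v == 0.0) return;
      double wD, wC;
      if (d + c < 170) {
        double denom = fact[d + c];
        wD = d > 0 ? fact[d - 1] * fact[c] / denom : 0.0;
        wC = c > 0 ? fact[d] * fact[c - 1] / denom : 0.0;
      } else {  // deep paths: log-gamma form avoids factorial overflow
        wD = d > 0 ? std::exp(std::lgamma(d) + std::lgamma(c + 1) -
                              std::lgamma(d + c + 1)) : 0.0;
        wC = c > 0 ? std::exp(std::lgamma(d + 1) + std::lgamma(c) -
                              std::lgamma(d + c + 1)) : 0.0;
      }
      for (int g : touched) {
        if (state[g] == 1) phi[g] += v * wD;
        else if (state[g] == 2) phi[g] -= v * wC;
      }
      return;
    }
    int fi = f - 1;
    double sp = tree.split[node - 1];
    int lt = (int)tree.left[node - 1], rt = (int)tree.right[node - 1];
    bool xl = x[fi] <= sp, bl = b[fi] <= sp;
    if (xl == bl) {
      walk(xl ? lt : rt);
      return;
    }
    int xchild = xl ? lt : rt, bchild = xl ? rt : lt;
    // branch where feature fi is taken from x
    if (state[fi] != 2) {
      bool fresh = state[fi] == 0;
      if (fresh) { state[fi] = 1; ++d; touched.push_back(fi); }
      walk(xchild);
      if (fresh) { state[fi] = 0; --d; touched.pop_back(); }
    }
    // branch where feature fi is taken from b
    if (state[fi] != 1) {
      bool fresh = state[fi] == 0;
      if (fresh) { state[fi] = 2; ++c; touched.push_back(fi); }
      walk(bchild);
      if (fresh) { state[fi] = 0; --c; touched.pop_back(); }
    }
  }
};

double leaf_value_for(const TreeView &t, const double *z) {
  int node = 1;
  while ((int)t.var[node - 1] != 0) {
    node = z[(int)t.var[node - 1] - 1] <= t.split[node - 1]
               ? (int)t.left[node - 1]
               : (int)t.right[node - 1];
  }
  return t.value[node - 1];
}

TreeView view_of(const NumericMatrix &m) {
  TreeView t;
  t.n = m.nrow();
  t.left = &m(0, 0);
  t.right = &m(0, 1);
  t.var = &m(0, 2);
  t.split = &m(0, 3);
  t.value = &m(0, 4);
  return t;
}

}  // namespace

// trees: list of matrices with columns [left, right, var, split, value]
// (1-based node/feature indices, 0 for leaf/none); ensemble prediction is
// the across-tree mean of leaf values. X: samples to explain. B:
// background rows. Returns phi (nrow(X) x p) and base (mean background
// prediction).
// [[Rcpp::export(.forest_shap_cpp)]]
List forest_shap_cpp(List trees, NumericMatrix X, NumericMatrix B) {
  int p = X.ncol(), nx = X.nrow(), nb = B.nrow(), nt = trees.size();
  if (B.ncol() != p) stop("background/feature dimension mismatch");
  std::vector<double> fact(258, 1.0);
  for (int i = 1; i < (int)fact.size(); ++i) fact[i] = fact[i - 1] * i;

  std::vector<NumericMatrix> tm;
  tm.reserve(nt);
  for (int t = 0; t < nt; ++t) tm.push_back(as<NumericMatrix>(trees[t]));

  NumericMatrix phi(nx, p);
  double base = 0.0;
  std::vector<double> xrow(p), brow(p), acc(p);

  for (int t = 0; t < nt; ++t) {
    TreeView tv = view_of(tm[t]);
    for (int ib = 0; ib < nb; ++ib) {
      for (int j = 0; j < p; ++j) brow[j] = B(ib, j);
      base += leaf_value_for(tv, brow.data());
      for (int ix = 0; ix < nx; ++ix) {
        for (int j = 0; j < p; ++j) xrow[j] = X(ix, j);
        std::fill(acc.begin(), acc.end(), 0.0);
        Walker w(tv, xrow.data(), brow.data(), p, acc.data(), fact);
        w.walk(1);
        for (int j = 0; j < p; ++j) phi(ix, j) += acc[j];
      }
    }
    Rcpp::checkUserInterrupt();
  }
  double scale = 1.0 / ((double)nt * nb);
  for (int ix = 0; ix < nx; ++ix)
    for (int j = 0; j < p; ++j) phi(ix, j) *= scale;
  base /= (double)nt * nb;
  return List::create(_["phi"] = phi, _["base"] = base);
}
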