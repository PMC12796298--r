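// Path-dependent TreeSHAP for binary gradient-boosted trees, computed in
// double precision so the local-accuracy identity (bias + sum of
// contributions = margin) holds to numerical round-off. Tree structures are
// handed over from R as parsed booster dumps; covers (training hessian
// sums) define the conditional expectations, exactly as in the reference
// algorithm.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> split;
  std::vector<int> yes, no, missing;
  std::vector<double> cover;
  std::vector<double> value;  // leaf value (0 for internal nodes)
};

struct PathElem {
  int d;      // feature index carried by this path element (-1 at root)
  double z;   // fraction of "zero" (feature hidden) paths that flow through
  double o;   // fraction of "one" (feature observed) paths
  double w;   // permutation weight
};

void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

void unwind_path(std::vector<PathElem> &m, int i) {
  int l = static_cast<int>(m.size()) - 1;
  double o = m[i].o, z = m[i].z;
  double n = m[l].w;
  if (o != 0.0) {
    for (int j = l - 1; j >= 0; --j) {
      double t = m[j].w;
      m[j].w = n * (l + 1) / ((j + 1) * o);
      n = t - m[j].w * z * (l - j) / static_cast<double>(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      m[j].w = m[j].w * (l + 1) / (z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

double unwound_sum(const std::vector<PathElem> &m, int i) {
  int l = static_cast<int>(m.size()) - 1;
  double o = m[i].o, z = m[i].z;
  double total = 0.0;
  if (o != 0.0) {
    double n = m[l].w;
    for (int j = l - 1; j >= 0; --j) {
      double t = n * (l + 1) / ((j + 1) * o);
      total += t;
      n = m[j].w - t * z * (l - j) / static_cast<double>(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      total += m[j].w * (l + 1) / (z * (l - j));
    }
  }
  return total;
}

void tree_shap_recurse(const Tree &tree, const double *x, double *phi,
                       int node, std::vector<PathElem> m,
                       double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  int f = tree.feature[node];
  if (f < 0) { // leaf
    double v = tree.value[node];
    for (size_t i = 1; i < m.size(); ++i) {
      double w = unwound_sum(m, static_cast<int>(i));
      phi[m[i].d] += w * (m[i].o - m[i].z) * v;
    }
    return;
  }
  double xv = x[f];
  int hot, cold;
  if (ISNAN(xv)) {
    hot = tree.missing[node];
  } else if (static_cast<float>(xv) < static_cast<float>(tree.split[node])) {
    // boosters store and compare split conditions in single precision
    hot = tree.yes[node];
  } else {
    hot = tree.no[node];
  }
  cold = (hot == tree.yes[node]) ? tree.no[node] : tree.yes[node];

  double iz = 1.0, io = 1.0;
  for (size_t k = 1; k < m.size(); ++k) {
    if (m[k].d == f) {
      iz = m[k].z;
      io = m[k].o;
      unwind_path(m, static_cast<int>(k));
      break;
    }
  }
  double rj = tree.cover[node];
  tree_shap_recurse(tree, x, phi, hot, m, iz * tree.cover[hot] / rj, io, f);
  tree_shap_recurse(tree, x, phi, cold, m, iz * tree.cover[cold] / rj, 0.0, f);
}

std::vector<Tree> build_trees(const List &trees_r) {
  std::vector<Tree> trees(trees_r.size());
  for (int t = 0; t < trees_r.size(); ++t) {
    List tr = trees_r[t];
    IntegerVector feature = tr["feature"];
    NumericVector split = tr["split"];
    IntegerVector yes = tr["yes"], no = tr["no"], missing = tr["missing"];
    NumericVector cover = tr["cover"], value = tr["value"];
    Tree &out = trees[t];
    out.feature.assign(feature.begin(), feature.end());
    out.split.assign(split.begin(), split.end());
    out.yes.assign(yes.begin(), yes.end());
    out.no.assign(no.begin(), no.end());
    out.missing.assign(missing.begin(), missing.end());
    out.cover.assign(cover.begin(), cover.end());
    out.value.assign(value.begin(), value.end());
  }
  return trees;
}

double leaf_expectation(const Tree &tree, int node) {
  if (tree.feature[node] < 0) return tree.value[node];
  double rj = tree.cover[node];
  return (tree.cover[tree.yes[node]] / rj) * leaf_expectation(tree, tree.yes[node]) +
         (tree.cover[tree.no[node]] / rj) * leaf_expectation(tree, tree.no[node]);
}

} // namespace

// [[Rcpp::export(name = ".tree_shap_cpp")]]
NumericMatrix tree_shap_cpp(List trees_r, NumericMatrix X) {
  std::vector<Tree> trees = build_trees(trees_r);
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p + 1); // last column: bias (expected margin)

  double base = 0.0;
  for (const Tree &tree : trees) base += leaf_expectation(tree, 0);

  std::vector<double> row(p), phi_row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    std::fill(phi_row.begin(), phi_row.end(), 0.0);
    for (const Tree &tree : trees) {
      tree_shap_recurse(tree, row.data(), phi_row.data(), 0,
                        std::vector<PathElem>(), 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phi_row[j];
    phi(i, p) = base;
  }
  return phi;
}

// [[Rcpp::export(name = ".tree_margin_cpp")]]
NumericVector tree_margin_cpp(List trees_r, NumericMatrix X) {
  std::vector<Tree> trees = build_trees(trees_r);
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    double total = 0.0;
    for (const Tree &tree : trees) {
      int node = 0;
      while (tree.feature[node] >= 0) {
        double xv = row[tree.feature[node]];
        if (ISNAN(xv)) node = tree.missing[node];
        else if (static_cast<float>(xv) < static_cast<float>(tree.split[node]))
          node = tree.yes[node]; // single-precision comparison, as the booster
        else node = tree.no[node];
      }
      total += tree.value[node];
    }
    out[i] = total;
  }
  return out;
}
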