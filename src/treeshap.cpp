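// Tree-path-dependent SHAP values for additive tree ensembles
// (the polynomial-time algorithm for exact Shapley values of a tree's
// cover-weighted conditional expectation). Validated in the test suite
// against a brute-force subset-enumeration Shapley oracle.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElem {
  int d;        // feature index of the split that created this entry (-1 root)
  double z;     // fraction of "zero" (cold) paths flowing through
  double o;     // 1 if the feature's hot branch matches x, else 0
  double w;     // permutation weight
};

struct Tree {
  const int *feature;      // -1 for leaves, else 0-based feature index
  const double *threshold;
  const int *left;         // 0-based child ids, -1 if none
  const int *right;
  const double *value;
  const double *cover;
};

void extend(std::vector<PathElem> &m, double pz, double po, int pi) {
  int l = (int)m.size();
  PathElem e;
  e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

void unwind(std::vector<PathElem> &m, int i) {
  int L = (int)m.size();
  double o = m[i].o, z = m[i].z;
  double n = m[L - 1].w;
  for (int j = L - 2; j >= 0; --j) {
    if (o != 0.0) {
      double t = m[j].w;
      m[j].w = n * L / ((j + 1) * o);
      n = t - m[j].w * z * (L - 1 - j) / (double)L;
    } else {
      m[j].w = m[j].w * L / (z * (L - 1 - j));
    }
  }
  for (int j = i; j < L - 1; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

double unwound_sum(const std::vector<PathElem> &m, int i) {
  int L = (int)m.size();
  double o = m[i].o, z = m[i].z;
  double n = m[L - 1].w;
  double total = 0.0;
  for (int j = L - 2; j >= 0; --j) {
    double neww;
    if (o != 0.0) {
      neww = n * L / ((j + 1) * o);
      n = m[j].w - neww * z * (L - 1 - j) / (double)L;
    } else {
      neww = m[j].w * L / (z * (L - 1 - j));
    }
    total += neww;
  }
  return total;
}

void recurse(const Tree &tr, int j, std::vector<PathElem> m,
             double pz, double po, int pi,
             const double *x, double *phi) {
  extend(m, pz, po, pi);
  if (tr.feature[j] < 0) {
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * tr.value[j];
    }
    return;
  }
  int d = tr.feature[j];
  int hot, cold;
  if (x[d] <= tr.threshold[j]) {
    hot = tr.left[j]; cold = tr.right[j];
  } else {
    hot = tr.right[j]; cold = tr.left[j];
  }
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == d) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind(m, k);
  }
  double rj = tr.cover[j];
  recurse(tr, hot, m, iz * tr.cover[hot] / rj, io, d, x, phi);
  recurse(tr, cold, m, iz * tr.cover[cold] / rj, 0.0, d, x, phi);
}

double expected_value(const Tree &tr, int j) {
  if (tr.feature[j] < 0) return tr.value[j];
  int l = tr.left[j], r = tr.right[j];
  return (tr.cover[l] * expected_value(tr, l) +
          tr.cover[r] * expected_value(tr, r)) / tr.cover[j];
}

} // namespace

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix X, List trees) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double expval = 0.0;
  int nt = trees.size();

  std::vector<double> xrow(p);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"];
    IntegerVector right = tl["right"];
    NumericVector value = tl["value"];
    NumericVector cover = tl["cover"];

    int nn = feature.size();
    std::vector<int> feat0(nn), l0(nn), r0(nn);
    for (int j = 0; j < nn; ++j) {
      feat0[j] = feature[j] > 0 ? feature[j] - 1 : -1;
      l0[j] = left[j] - 1;   // -1 when absent (0 in R)
      r0[j] = right[j] - 1;
    }
    Tree tr;
    tr.feature = feat0.data();
    tr.threshold = REAL(threshold);
    tr.left = l0.data();
    tr.right = r0.data();
    tr.value = REAL(value);
    tr.cover = REAL(cover);

    expval += expected_value(tr, 0);

    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::vector<PathElem> m;
      m.reserve(16);
      std::vector<double> phirow(p, 0.0);
      recurse(tr, 0, m, 1.0, 1.0, -1, xrow.data(), phirow.data());
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j];
    }
  }
  return List::create(_["phi"] = phi, _["expected_value"] = expval);
}
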