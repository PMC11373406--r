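#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Split score (Fixation-Index-style ratio)
//
// For a candidate feature x at a node split into children L and R:
//   D_box(child) = sum_{i != j} (x_i - x_j)^2 / (N (N - 1))   (ordered pairs)
//   D_nabla     = sum_{i in L, j in R} (x_i - x_j)^2 / (N_L N_R)
//   score       = (D_box(L) + D_box(R)) / 2 / D_nabla
// Small scores indicate tight children far apart; 0 is perfect separation.
// A singleton child contributes D_box = 0. D_nabla == 0 means the split is
// degenerate (all values identical across children) and is reported NA.
//
// Both quantities reduce to sums and sums of squares:
//   sum_{i != j} (x_i - x_j)^2          = 2 N q - 2 s^2
//   sum_{i in L, j in R} (x_i - x_j)^2  = N_R q_L + N_L q_R - 2 s_L s_R
// with s = sum(x), q = sum(x^2) per child.
// ---------------------------------------------------------------------------

static inline double score_from_moments(double nL, double nR,
                                        double sL, double sR,
                                        double qL, double qR) {
  double dL = 0.0, dR = 0.0;
  if (nL > 1.0) dL = (2.0 * nL * qL - 2.0 * sL * sL) / (nL * (nL - 1.0));
  if (nR > 1.0) dR = (2.0 * nR * qR - 2.0 * sR * sR) / (nR * (nR - 1.0));
  if (dL < 0.0) dL = 0.0;  // guard against rounding
  if (dR < 0.0) dR = 0.0;
  double cross = nR * qL + nL * qR - 2.0 * sL * sR;
  double dn = cross / (nL * nR);
  if (dn <= 0.0) return NA_REAL;
  return 0.5 * (dL + dR) / dn;
}

// Numerically stable evaluation via centered two-pass sums:
//   sum_{i != j} (x_i - x_j)^2          = 2 N sum_i (x_i - mu)^2
//   sum_{i in L, j in R} (x_i - x_j)^2  = N_R ssq_L + N_L ssq_R
//                                         + N_L N_R (mu_L - mu_R)^2
// [[Rcpp::export(name = ".delta_f_cpp")]]
double delta_f_cpp(NumericVector x, LogicalVector left) {
  if (x.size() != left.size())
    stop("'x' and 'left' must have the same length");
  double nL = 0, nR = 0, sL = 0, sR = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (NumericVector::is_na(x[i]) || !R_finite(x[i]))
      stop("'x' must be finite");
    if (left[i]) { nL += 1; sL += x[i]; } else { nR += 1; sR += x[i]; }
  }
  if (nL == 0 || nR == 0) stop("both children must be nonempty");
  double muL = sL / nL, muR = sR / nR, ssqL = 0, ssqR = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double c = left[i] ? x[i] - muL : x[i] - muR;
    if (left[i]) ssqL += c * c; else ssqR += c * c;
  }
  double dL = nL > 1 ? 2.0 * ssqL / (nL - 1.0) : 0.0;
  double dR = nR > 1 ? 2.0 * ssqR / (nR - 1.0) : 0.0;
  double dn = (nR * ssqL + nL * ssqR) / (nL * nR) +
    (muL - muR) * (muL - muR);
  if (dn <= 0.0) return NA_REAL;
  return 0.5 * (dL + dR) / dn;
}

// Best split for one feature within a node: scan thresholds at midpoints
// between consecutive distinct sorted values, honouring the leaf-size
// constraint. Returns true if a valid split improves on *best_score.
// sign = +1 minimizes the score, -1 maximizes it.
static bool scan_feature(const std::vector<double>& v, int min_leaf,
                         double sign, double* best_score, double* best_thr) {
  const int n = (int)v.size();
  std::vector<double> sv(v);
  std::sort(sv.begin(), sv.end());
  // center on the node mean (the score is shift-invariant) so the
  // moment-based prefix sums do not cancel catastrophically
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += sv[i];
  mu /= n;
  std::vector<double> ps(n + 1, 0.0), pq(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double c = sv[i] - mu;
    ps[i + 1] = ps[i] + c;
    pq[i + 1] = pq[i] + c * c;
  }
  bool improved = false;
  for (int s = min_leaf; s <= n - min_leaf; ++s) {
    if (sv[s - 1] == sv[s]) continue;  // not a boundary between distinct values
    double sc = score_from_moments((double)s, (double)(n - s),
                                   ps[s], ps[n] - ps[s],
                                   pq[s], pq[n] - pq[s]);
    if (ISNA(sc)) continue;
    if (sign * sc < *best_score) {
      *best_score = sign * sc;
      *best_thr = 0.5 * (sv[s - 1] + sv[s]);
      improved = true;
    }
  }
  return improved;
}

// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, IntegerVector candidates, int min_leaf,
                    bool maximize = false) {
  const int n = X.nrow();
  const double sign = maximize ? -1.0 : 1.0;
  double best_score = R_PosInf, best_thr = NA_REAL;
  int best_feat = NA_INTEGER;
  std::vector<double> v(n);
  // candidates assumed sorted ascending (1-based); strict '<' in scan_feature
  // breaks ties toward the lowest feature index, then the lowest threshold.
  for (int ci = 0; ci < candidates.size(); ++ci) {
    int f = candidates[ci] - 1;
    for (int i = 0; i < n; ++i) v[i] = X(i, f);
    if (scan_feature(v, min_leaf, sign, &best_score, &best_thr))
      best_feat = candidates[ci];
  }
  return List::create(_["feature"] = best_feat,
                      _["threshold"] = best_thr,
                      _["score"] = best_feat == NA_INTEGER ? NA_REAL
                                                           : sign * best_score);
}

// ---------------------------------------------------------------------------
// Tree growing
// ---------------------------------------------------------------------------

struct TreeBuilder {
  const NumericMatrix& X;
  int mtry, min_leaf, p;
  double sign;
  std::vector<int> pool;  // feature pool for mtry sampling (0-based)
  // flat node arrays (1-based child links, NA for absent)
  std::vector<int> feature, left, right, leaf_id, n_train;
  std::vector<double> threshold;
  int next_leaf;

  TreeBuilder(const NumericMatrix& X_, int mtry_, int min_leaf_, double sign_)
      : X(X_), mtry(mtry_), min_leaf(min_leaf_), p(X_.ncol()), sign(sign_),
        pool(p), next_leaf(0) {
    for (int j = 0; j < p; ++j) pool[j] = j;
  }

  int new_node() {
    feature.push_back(NA_INTEGER);
    threshold.push_back(NA_REAL);
    left.push_back(NA_INTEGER);
    right.push_back(NA_INTEGER);
    leaf_id.push_back(NA_INTEGER);
    n_train.push_back(NA_INTEGER);
    return (int)feature.size() - 1;
  }

  // sample mtry distinct features uniformly (partial Fisher-Yates using R RNG),
  // returned sorted ascending for deterministic tie-breaking
  void sample_features(std::vector<int>& out) {
    int m = std::min(mtry, p);
    out.resize(m);
    for (int j = 0; j < m; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(pool[j], pool[r]);
      out[j] = pool[j];
    }
    std::sort(out.begin(), out.end());
  }

  // idx: training-sample rows (0-based) reaching this node
  int build(std::vector<int>& idx) {
    int node = new_node();
    const int n = (int)idx.size();
    bool is_leaf = true;
    if (n >= 2 * min_leaf) {
      std::vector<int> cand;
      sample_features(cand);
      double best_score = R_PosInf, best_thr = NA_REAL;
      int best_feat = -1;
      std::vector<double> v(n);
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        int f = cand[ci];
        for (int i = 0; i < n; ++i) v[i] = X(idx[i], f);
        if (scan_feature(v, min_leaf, sign, &best_score, &best_thr)) best_feat = f;
      }
      if (best_feat >= 0) {
        is_leaf = false;
        std::vector<int> li, ri;
        li.reserve(n); ri.reserve(n);
        for (int i = 0; i < n; ++i) {
          if (X(idx[i], best_feat) <= best_thr) li.push_back(idx[i]);
          else ri.push_back(idx[i]);
        }
        feature[node] = best_feat + 1;  // 1-based for R
        threshold[node] = best_thr;
        int l = build(li);
        int r = build(ri);
        left[node] = l + 1;
        right[node] = r + 1;
      }
    }
    if (is_leaf) {
      leaf_id[node] = ++next_leaf;  // consecutive, 1-based
      n_train[node] = n;
    }
    return node;
  }

  List as_list() {
    return List::create(_["feature"] = wrap(feature),
                        _["threshold"] = wrap(threshold),
                        _["left"] = wrap(left),
                        _["right"] = wrap(right),
                        _["leaf_id"] = wrap(leaf_id),
                        _["n_train"] = wrap(n_train));
  }
};

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, int n_trees, int mtry, int min_leaf,
                     bool bootstrap, bool maximize = false) {
  const int n = X.nrow();
  if (n < 1) stop("need at least one sample");
  const double sign = maximize ? -1.0 : 1.0;
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    TreeBuilder tb(X, mtry, min_leaf, sign);
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int r = (int)(unif_rand() * n);
        if (r >= n) r = n - 1;
        idx[i] = r;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    tb.build(idx);
    forest[t] = tb.as_list();
  }
  return forest;
}

// ---------------------------------------------------------------------------
// Leaf propagation and co-occurrence counting
// ---------------------------------------------------------------------------

static void leaf_ids_one(const List& tree, const NumericMatrix& X, int* out) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  IntegerVector leaf_id = tree["leaf_id"];
  const int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int f = feature[node] - 1;
      if (f < 0 || f >= p)
        stop("tree references feature %d but data has %d columns",
             feature[node], p);
      node = (X(i, f) <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = leaf_id[node];
  }
}

// [[Rcpp::export(name = ".leaf_ids_cpp")]]
IntegerVector leaf_ids_cpp(List tree, NumericMatrix X) {
  IntegerVector out(X.nrow());
  leaf_ids_one(tree, X, INTEGER(out));
  return out;
}

// [[Rcpp::export(name = ".leaf_matrix_cpp")]]
IntegerMatrix leaf_matrix_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t)
    leaf_ids_one(forest[t], X, &out[(R_xlen_t)t * n]);
  return out;
}

// Sum over trees of the binary same-leaf indicator (diagonal included).
// [[Rcpp::export(name = ".forest_counts_cpp")]]
IntegerMatrix forest_counts_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  if (T < 1) stop("forest has no trees");
  IntegerMatrix counts(n, n);
  std::vector<int> leaves(n);
  for (int t = 0; t < T; ++t) {
    leaf_ids_one(forest[t], X, leaves.data());
    int n_leaves = 0;
    for (int i = 0; i < n; ++i) n_leaves = std::max(n_leaves, leaves[i]);
    std::vector< std::vector<int> > members(n_leaves);
    for (int i = 0; i < n; ++i) members[leaves[i] - 1].push_back(i);
    for (int l = 0; l < n_leaves; ++l) {
      const std::vector<int>& m = members[l];
      for (size_t a = 0; a < m.size(); ++a)
        for (size_t b = 0; b < m.size(); ++b)
          counts(m[a], m[b]) += 1;
    }
  }
  return counts;
}
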