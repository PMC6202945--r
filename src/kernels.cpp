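#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Nonlinear time-series measures
// ---------------------------------------------------------------------------

// Sample entropy with embedding dimension m and tolerance r (absolute units,
// Chebyshev distance). Returns -log(A/B); NA when undefined.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2 || r <= 0) return NA_REAL;
  long long B = 0, A = 0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d >= r) { okm = false; break; }
      }
      if (!okm) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) < r) ++A;
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Higuchi fractal dimension with maximum delay kmax.
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  int n = x.size();
  if (n < kmax * 3) return NA_REAL;
  std::vector<double> lk(kmax), lnk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k;
      if (nm < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= nm; ++i)
        L += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      L *= (double)(n - 1) / ((double)nm * k * k);
      lsum += L;
    }
    lk[k - 1] = std::log(lsum / k > 0 ? lsum / k : 1e-300);
    lnk[k - 1] = std::log(1.0 / k);
  }
  // least squares slope of lk on lnk
  double mx = 0, my = 0;
  for (int i = 0; i < kmax; ++i) { mx += lnk[i]; my += lk[i]; }
  mx /= kmax; my /= kmax;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < kmax; ++i) {
    sxy += (lnk[i] - mx) * (lk[i] - my);
    sxx += (lnk[i] - mx) * (lnk[i] - mx);
  }
  if (sxx <= 0) return NA_REAL;
  return sxy / sxx;
}

// Recurrence period density entropy. Embeds x (dimension m, delay tau),
// finds for each point the first return time into an eps-ball around it, and
// returns the normalized Shannon entropy of the return-time histogram plus
// the recurrence rate (fraction of pairs within eps) via `out`.
// [[Rcpp::export(name = ".rpde_cpp")]]
List rpde_cpp(NumericVector x, int m, int tau, double eps, int tmax) {
  int n = x.size() - (m - 1) * tau;
  if (n < 10 || eps <= 0) return List::create(_["rpde"] = NA_REAL,
                                              _["rec_rate"] = NA_REAL);
  std::vector<long long> hist(tmax + 1, 0);
  long long npairs = 0, nrec = 0;
  for (int i = 0; i < n; ++i) {
    for (int t = 1; t <= tmax && i + t < n; ++t) {
      double d = 0.0;
      for (int k = 0; k < m; ++k)
        d = std::max(d, std::fabs(x[i + k * tau] - x[i + t + k * tau]));
      ++npairs;
      if (d < eps) { ++nrec; ++hist[t]; break; }
    }
  }
  double tot = 0;
  for (int t = 1; t <= tmax; ++t) tot += hist[t];
  double H = 0;
  if (tot > 0) {
    for (int t = 1; t <= tmax; ++t) {
      if (hist[t] > 0) {
        double p = hist[t] / tot;
        H -= p * std::log(p);
      }
    }
    H /= std::log((double)tmax);
  } else {
    H = NA_REAL;
  }
  double rr = npairs > 0 ? (double)nrec / (double)npairs : NA_REAL;
  return List::create(_["rpde"] = H, _["rec_rate"] = rr);
}

// Recurrence rate of the embedded series: fraction of sampled point pairs
// closer than eps (Chebyshev), subsampled for large n.
// [[Rcpp::export(name = ".recurrence_rate_cpp")]]
double recurrence_rate_cpp(NumericVector x, int m, int tau, double eps,
                           int max_points) {
  int n = x.size() - (m - 1) * tau;
  if (n < 10 || eps <= 0) return NA_REAL;
  int step = std::max(1, n / max_points);
  long long npairs = 0, nrec = 0;
  for (int i = 0; i < n; i += step) {
    for (int j = i + step; j < n; j += step) {
      double d = 0.0;
      for (int k = 0; k < m; ++k)
        d = std::max(d, std::fabs(x[i + k * tau] - x[j + k * tau]));
      ++npairs;
      if (d < eps) ++nrec;
    }
  }
  return npairs > 0 ? (double)nrec / (double)npairs : NA_REAL;
}

// ---------------------------------------------------------------------------
// Random forest (binary classification, Gini CART, bootstrap + mtry)
// ---------------------------------------------------------------------------

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob1 = 0.5;     // leaf: P(class 1)
};

struct Tree { std::vector<Node> nodes; };

static void grow_node(const NumericMatrix& X, const IntegerVector& y,
                      std::vector<int>& idx, int lo, int hi, int node_id,
                      Tree& tree, int mtry, int min_node, int depth,
                      std::mt19937& rng) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  Node& node = tree.nodes[node_id];
  node.prob1 = n > 0 ? (double)n1 / n : 0.5;
  if (n < min_node || n1 == 0 || n1 == n || depth > 30) return;

  int p = X.ncol();
  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> u(j, p - 1);
    std::swap(feats[j], feats[u(rng)]);
  }
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  double parent_imp = 2.0 * node.prob1 * (1.0 - node.prob1) * n;
  std::vector<std::pair<double, int>> vals(n);
  for (int fj = 0; fj < mtry && fj < p; ++fj) {
    int f = feats[fj];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      int r1 = n1 - l1;
      double pl = (double)l1 / nl, pr = (double)r1 / nr;
      double imp = 2.0 * pl * (1.0 - pl) * nl + 2.0 * pr * (1.0 - pr) * nr;
      double gain = parent_imp - imp;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;
  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;
  int left_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  int right_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].threshold = best_thr;
  tree.nodes[node_id].left = left_id;
  tree.nodes[node_id].right = right_id;
  grow_node(X, y, idx, lo, mid, left_id, tree, mtry, min_node, depth + 1, rng);
  grow_node(X, y, idx, mid, hi, right_id, tree, mtry, min_node, depth + 1, rng);
}

static double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold)
            ? tree.nodes[cur].left : tree.nodes[cur].right;
  }
  return tree.nodes[cur].prob1;
}

// Train a random forest on (X, y in {0,1}) and return P(class 1) for each
// row of Xtest. ntree bootstrap CART trees, mtry features per split.
// [[Rcpp::export(name = ".rf_cpp")]]
NumericVector rf_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                     int ntree, int mtry, int min_node, int seed) {
  int n = X.nrow();
  int ntest = Xtest.nrow();
  if (mtry < 1) mtry = 1;
  std::mt19937 rng((unsigned)seed);
  NumericVector out(ntest, 0.0);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    tree.nodes.push_back(Node());
    grow_node(X, y, idx, 0, n, 0, tree, mtry, min_node, 0, rng);
    for (int i = 0; i < ntest; ++i) out[i] += predict_tree(tree, Xtest, i);
  }
  for (int i = 0; i < ntest; ++i) out[i] /= ntree;
  return out;
}

// ---------------------------------------------------------------------------
// Feature-weighting kernels for the selection ensemble
// ---------------------------------------------------------------------------

// ReliefF weights for a binary problem: k nearest hits / misses per sample
// under L1 distance on the (pre-standardized) feature matrix.
// [[Rcpp::export(name = ".relief_cpp")]]
NumericVector relief_cpp(NumericMatrix X, IntegerVector y, int k) {
  int n = X.nrow(), p = X.ncol();
  NumericVector w(p, 0.0);
  if (n < 3) return w;
  // transpose so each sample's features are contiguous
  std::vector<double> Xt((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < p; ++f) Xt[(size_t)i * p + f] = X(i, f);
  std::vector<double> d(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt[(size_t)i * p];
    for (int j = 0; j < n; ++j) {
      if (j == i) { d[j] = 1e300; continue; }
      const double* xj = &Xt[(size_t)j * p];
      double s = 0.0;
      for (int f = 0; f < p; ++f) s += std::fabs(xi[f] - xj[f]);
      d[j] = s;
    }
    for (int j = 0; j < n; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d[a] < d[b]; });
    int nh = 0, nm = 0;
    for (int jj = 0; jj < n && (nh < k || nm < k); ++jj) {
      int j = ord[jj];
      if (j == i) continue;
      const double* xi = &Xt[(size_t)i * p];
      const double* xj = &Xt[(size_t)j * p];
      bool hit = (y[j] == y[i]);
      if (hit && nh < k) {
        for (int f = 0; f < p; ++f) w[f] -= std::fabs(xi[f] - xj[f]);
        ++nh;
      } else if (!hit && nm < k) {
        for (int f = 0; f < p; ++f) w[f] += std::fabs(xi[f] - xj[f]);
        ++nm;
      }
    }
  }
  for (int f = 0; f < p; ++f) w[f] /= n;
  return w;
}

// Local-learning-based feature selection: iteratively reweighted margin
// (probabilistic nearest hit/miss under the current weighted L1 metric),
// with a projected-gradient update of nonnegative weights on a logistic
// margin loss with L1 shrinkage.
// [[Rcpp::export(name = ".llbfs_cpp")]]
NumericVector llbfs_cpp(NumericMatrix X, IntegerVector y, int iters,
                        double lambda) {
  int n = X.nrow(), p = X.ncol();
  NumericVector w(p, 1.0 / p);
  if (n < 4) return w;
  std::vector<double> Xt((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < p; ++f) Xt[(size_t)i * p + f] = X(i, f);
  std::vector<double> D((size_t)n * n), ph(n), pm(n), m(p), g(p);
  for (int it = 0; it < iters; ++it) {
    std::fill(g.begin(), g.end(), 0.0);
    double mean_d = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &Xt[(size_t)i * p];
      D[(size_t)i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        const double* xj = &Xt[(size_t)j * p];
        double s = 0.0;
        for (int f = 0; f < p; ++f) s += w[f] * std::fabs(xi[f] - xj[f]);
        D[(size_t)i * n + j] = s;
        D[(size_t)j * n + i] = s;
        mean_d += 2.0 * s;
      }
    }
    double sigma = n > 1 ? mean_d / ((double)n * (n - 1)) : 1.0;
    if (sigma <= 0) sigma = 1.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &Xt[(size_t)i * p];
      double sh = 0.0, sm = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { ph[j] = pm[j] = 0; continue; }
        double e = std::exp(-D[(size_t)i * n + j] / sigma);
        if (y[j] == y[i]) { ph[j] = e; sh += e; pm[j] = 0; }
        else { pm[j] = e; sm += e; ph[j] = 0; }
      }
      if (sh <= 0 || sm <= 0) continue;
      std::fill(m.begin(), m.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double c = pm[j] / sm - ph[j] / sh;
        if (c == 0.0) continue;
        const double* xj = &Xt[(size_t)j * p];
        for (int f = 0; f < p; ++f)
          m[f] += c * std::fabs(xi[f] - xj[f]);
      }
      double wm = 0.0;
      for (int f = 0; f < p; ++f) wm += w[f] * m[f];
      double sig = 1.0 / (1.0 + std::exp(wm));   // sigmoid(-w.m)
      for (int f = 0; f < p; ++f) g[f] += sig * m[f];
    }
    double eta = 1.0 / n;
    double ssum = 0.0;
    for (int f = 0; f < p; ++f) {
      w[f] += eta * (g[f] / n) - eta * lambda;
      if (w[f] < 0) w[f] = 0;
      ssum += w[f];
    }
    if (ssum <= 0) { std::fill(w.begin(), w.end(), 1.0 / p); }
    else for (int f = 0; f < p; ++f) w[f] /= ssum;
  }
  return w;
}
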