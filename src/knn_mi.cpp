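#include <Rcpp.h>
#include <vector>
#include <memory>
#include <algorithm>
#include <cmath>

// Kraskov variant-1 mutual information needs, for every sample, the
// Chebyshev (max-norm) distance to its k-th neighbour in the joint space and
// strict range counts within that radius in each marginal space.  A kd-tree
// with per-node bounding boxes supports both queries under the max norm.
// Points are reordered into leaf-contiguous storage at build time so leaf
// scans are cache-friendly; the k-best set is kept in a small insertion-
// sorted array (k is single-digit in practice).

namespace {

constexpr int LEAF = 24;

struct KBest {
  int k, size;
  double d[64];
  explicit KBest(int k_) : k(k_), size(0) {}
  double worst() const { return size == k ? d[k - 1] : R_PosInf; }
  void push(double v) {
    int i = size < k ? size : k - 1;
    if (size < k) ++size;
    while (i > 0 && d[i - 1] > v) { d[i] = d[i - 1]; --i; }
    d[i] = v;
  }
};

struct KDTree {
  int n, dim;
  std::vector<double> pts;   // row-major, leaf-contiguous order
  std::vector<int> orig;     // position in storage order -> original index
  std::vector<int> left, right, start, end;
  std::vector<double> lo, hi;

  KDTree(const double *src, int n_, int dim_) : n(n_), dim(dim_) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    left.reserve(2 * n / LEAF + 4); right.reserve(2 * n / LEAF + 4);
    start.reserve(2 * n / LEAF + 4); end.reserve(2 * n / LEAF + 4);
    build(src, idx, 0, n);
    pts.resize((size_t)n * dim);
    orig = idx;
    for (int i = 0; i < n; ++i)
      std::copy(src + (size_t)idx[i] * dim, src + (size_t)idx[i] * dim + dim,
                &pts[(size_t)i * dim]);
  }

  int new_node(const double *src, const std::vector<int> &idx, int s, int e) {
    int id = (int)left.size();
    left.push_back(-1); right.push_back(-1);
    start.push_back(s); end.push_back(e);
    lo.resize(lo.size() + dim, R_PosInf);
    hi.resize(hi.size() + dim, R_NegInf);
    double *l = &lo[(size_t)id * dim], *h = &hi[(size_t)id * dim];
    for (int i = s; i < e; ++i) {
      const double *q = src + (size_t)idx[i] * dim;
      for (int d = 0; d < dim; ++d) {
        if (q[d] < l[d]) l[d] = q[d];
        if (q[d] > h[d]) h[d] = q[d];
      }
    }
    return id;
  }

  int build(const double *src, std::vector<int> &idx, int s, int e) {
    int id = new_node(src, idx, s, e);
    if (e - s <= LEAF) return id;
    const double *l = &lo[(size_t)id * dim], *h = &hi[(size_t)id * dim];
    int sd = 0; double w = -1.0;
    for (int d = 0; d < dim; ++d)
      if (h[d] - l[d] > w) { w = h[d] - l[d]; sd = d; }
    if (w <= 0.0) return id;  // all points identical: keep as leaf
    int mid = s + (e - s) / 2;
    std::nth_element(idx.begin() + s, idx.begin() + mid, idx.begin() + e,
                     [&](int a, int b) {
                       return src[(size_t)a * dim + sd] < src[(size_t)b * dim + sd];
                     });
    int lc = build(src, idx, s, mid);
    int rc = build(src, idx, mid, e);
    left[id] = lc; right[id] = rc;
    return id;
  }

  // Chebyshev distance from q to the node's box (0 if inside); returns
  // early with a value >= cap as soon as the bound crosses it
  double box_dist(int node, const double *q, double cap = R_PosInf) const {
    const double *l = &lo[(size_t)node * dim], *h = &hi[(size_t)node * dim];
    double m = 0.0;
    for (int d = 0; d < dim; ++d) {
      double v = l[d] - q[d];
      if (q[d] - h[d] > v) v = q[d] - h[d];
      if (v > m) {
        m = v;
        if (m >= cap) return m;
      }
    }
    return m;
  }

  double box_maxdist(int node, const double *q, double cap = R_PosInf) const {
    const double *l = &lo[(size_t)node * dim], *h = &hi[(size_t)node * dim];
    double m = 0.0;
    for (int d = 0; d < dim; ++d) {
      double v = q[d] - l[d];
      if (h[d] - q[d] > v) v = h[d] - q[d];
      if (v > m) {
        m = v;
        if (m >= cap) return m;
      }
    }
    return m;
  }

  double pt_dist(int j, const double *q, double cap) const {
    const double *p = &pts[(size_t)j * dim];
    double m = 0.0;
    for (int d = 0; d < dim; ++d) {
      double v = std::fabs(p[d] - q[d]);
      if (v > m) {
        m = v;
        if (m >= cap) return R_PosInf;
      }
    }
    return m;
  }

  // self_orig: original index of the query point; points with original
  // index within `theiler` of it are excluded (self included, theiler >= 0)
  void knn(int node, const double *q, int self_orig, int theiler,
           KBest &best) const {
    if (left[node] < 0) {
      for (int j = start[node]; j < end[node]; ++j) {
        if (std::abs(orig[j] - self_orig) <= theiler) continue;
        double d = pt_dist(j, q, best.worst());
        if (d < best.worst()) best.push(d);
      }
      return;
    }
    int a = left[node], b = right[node];
    double w = best.worst();
    double da = box_dist(a, q, w), db = box_dist(b, q, w);
    if (db < da) { std::swap(a, b); std::swap(da, db); }
    if (da < w) knn(a, q, self_orig, theiler, best);
    if (db < best.worst()) knn(b, q, self_orig, theiler, best);
  }

  double kth_dist(const double *q, int self_orig, int k, int theiler) const {
    KBest best(k);
    knn(0, q, self_orig, theiler, best);
    return best.d[k - 1];
  }

  // number of points with max-norm distance strictly below r (self included)
  int count_within(int node, const double *q, double r) const {
    if (box_dist(node, q, r) >= r) return 0;
    if (box_maxdist(node, q, r) < r) return end[node] - start[node];
    if (left[node] < 0) {
      int c = 0;
      for (int j = start[node]; j < end[node]; ++j)
        if (pt_dist(j, q, r) < r) ++c;
      return c;
    }
    return count_within(left[node], q, r) + count_within(right[node], q, r);
  }
};

// exact strict range count on a sorted 1-d marginal: binary search gives the
// approximate window, the boundary is then settled with the same |v - q| < r
// predicate the trees and the brute-force oracle use, so floating-point
// rounding of q +/- r cannot shift the count
int count_sorted(const std::vector<double> &v, double q, double r) {
  int n = (int)v.size();
  int i1 = (int)(std::upper_bound(v.begin(), v.end(), q - r) - v.begin());
  while (i1 > 0 && std::fabs(v[i1 - 1] - q) < r) --i1;
  while (i1 < n && !(std::fabs(v[i1] - q) < r)) ++i1;
  int i2 = (int)(std::lower_bound(v.begin(), v.end(), q + r) - v.begin());
  while (i2 < n && std::fabs(v[i2] - q) < r) ++i2;
  while (i2 > i1 && !(std::fabs(v[i2 - 1] - q) < r)) --i2;
  return i2 - i1;
}

std::vector<double> to_rowmajor(const Rcpp::NumericMatrix &m) {
  int n = m.nrow(), dim = m.ncol();
  std::vector<double> out((size_t)n * dim);
  for (int j = 0; j < dim; ++j)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * dim + j] = m(i, j);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(Rcpp::NumericMatrix x, Rcpp::NumericMatrix y, int k,
                  int theiler = 0) {
  int n = x.nrow();
  int dx = x.ncol(), dy = y.ncol();
  if (y.nrow() != n) Rcpp::stop("sample counts differ");
  if (k < 1 || k >= n) Rcpp::stop("k must satisfy 1 <= k < n");
  if (k > 63) Rcpp::stop("k must be <= 63");
  if (theiler < 0) Rcpp::stop("theiler must be >= 0");
  if (n - 2 * theiler <= k)
    Rcpp::stop("theiler window leaves fewer than k eligible neighbours");

  std::vector<double> px = to_rowmajor(x);
  std::vector<double> py = to_rowmajor(y);
  std::vector<double> pj((size_t)n * (dx + dy));
  for (int i = 0; i < n; ++i) {
    std::copy(&px[(size_t)i * dx], &px[(size_t)i * dx] + dx,
              &pj[(size_t)i * (dx + dy)]);
    std::copy(&py[(size_t)i * dy], &py[(size_t)i * dy] + dy,
              &pj[(size_t)i * (dx + dy)] + dx);
  }

  KDTree tj(pj.data(), n, dx + dy);
  // 1-d marginals use sorted binary search instead of a tree
  std::unique_ptr<KDTree> tx, ty;
  std::vector<double> sx, sy;
  if (dx == 1) { sx = px; std::sort(sx.begin(), sx.end()); }
  else tx.reset(new KDTree(px.data(), n, dx));
  if (dy == 1) { sy = py; std::sort(sy.begin(), sy.end()); }
  else ty.reset(new KDTree(py.data(), n, dy));

  // map original index -> storage order in each marginal tree, so the self
  // point can be excluded by count arithmetic (it is always within range)
  double acc = 0.0, accN = 0.0;
  for (int s = 0; s < n; ++s) {
    // iterate in joint-tree storage order: consecutive queries are close in
    // space, keeping the traversal warm in cache
    const double *qj = &tj.pts[(size_t)s * (dx + dy)];
    int i = tj.orig[s];
    double eps = tj.kth_dist(qj, i, k, theiler);
    if (eps <= 0.0)
      Rcpp::stop("tied samples (zero k-th neighbour distance); add jitter");
    int nx = (dx == 1 ? count_sorted(sx, px[i], eps)
                      : tx->count_within(0, &px[(size_t)i * dx], eps));
    int ny = (dy == 1 ? count_sorted(sy, py[i], eps)
                      : ty->count_within(0, &py[(size_t)i * dy], eps));
    // subtract the excluded temporal window (self included) from the counts
    int w_lo = std::max(0, i - theiler), w_hi = std::min(n - 1, i + theiler);
    for (int j = w_lo; j <= w_hi; ++j) {
      double mx = 0.0, my = 0.0;
      for (int d = 0; d < dx; ++d) {
        double v = std::fabs(px[(size_t)j * dx + d] - px[(size_t)i * dx + d]);
        if (v > mx) mx = v;
      }
      if (mx < eps) --nx;
      for (int d = 0; d < dy; ++d) {
        double v = std::fabs(py[(size_t)j * dy + d] - py[(size_t)i * dy + d]);
        if (v > my) my = v;
      }
      if (my < eps) --ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
    // effective sample count: total minus excluded window beyond self, so
    // the theiler = 0 case reduces exactly to psi(n)
    accN += R::digamma((double)(n - (w_hi - w_lo + 1) + 1));
  }
  double mi_nats = R::digamma((double)k) + accN / n - acc / n;
  return mi_nats / std::log(2.0);
}
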