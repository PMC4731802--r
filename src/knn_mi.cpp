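#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information, algorithm 1.
//
// Distances are Chebyshev (max-norm) in both the joint and the marginal
// spaces.  For each sample the k-th nearest joint neighbour distance
// eps_i is located with a kd-tree over the joint space, then n_x(i) and
// n_y(i) count samples strictly inside eps_i in each marginal (kd-trees
// again).  I = psi(k) + psi(n) - <psi(nx+1) + psi(ny+1)>.

namespace {

// kd-tree over row-major points, median split, implicit node ranges
class KDTree {
 public:
  void build(const std::vector<double>& pts, int n, int dim) {
    pts_ = &pts;
    n_ = n;
    dim_ = dim;
    idx_.resize(n);
    for (int i = 0; i < n; ++i) idx_[i] = i;
    build_rec(0, n, 0);
  }

  // distance to the k-th nearest neighbour of point q (excluding sample
  // `self`), max-norm
  double knn_dist(const double* q, int self, int k) const {
    heap_.clear();
    worst_ = R_PosInf;
    k_ = k;
    self_ = self;
    knn_rec(0, n_, 0, q);
    return worst_;
  }

  // number of samples j != self with max-norm distance strictly < eps
  int count_within(const double* q, int self, double eps) const {
    int cnt = 0;
    count_rec(0, n_, 0, q, self, eps, cnt);
    return cnt;
  }

 private:
  const std::vector<double>* pts_ = nullptr;
  int n_ = 0, dim_ = 0;
  std::vector<int> idx_;
  mutable std::vector<double> heap_;
  mutable double worst_ = R_PosInf;
  mutable int k_ = 0, self_ = -1;

  inline double coord(int i, int d) const { return (*pts_)[i * dim_ + d]; }

  inline double dist(const double* q, int i, double bound) const {
    double m = 0.0;
    for (int d = 0; d < dim_; ++d) {
      double v = std::fabs(coord(i, d) - q[d]);
      if (v > m) m = v;
      if (m >= bound) return m;
    }
    return m;
  }

  void build_rec(int lo, int hi, int depth) {
    if (hi - lo <= LEAF) return;
    const int d = depth % dim_;
    const int mid = (lo + hi) / 2;
    const std::vector<double>& p = *pts_;
    const int dim = dim_;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&p, d, dim](int a, int b) {
                       return p[a * dim + d] < p[b * dim + d];
                     });
    build_rec(lo, mid, depth + 1);
    build_rec(mid + 1, hi, depth + 1);
  }

  void knn_rec(int lo, int hi, int depth, const double* q) const {
    if (hi - lo <= LEAF) {
      for (int p = lo; p < hi; ++p) offer(q, idx_[p]);
      return;
    }
    const int d = depth % dim_;
    const int mid = (lo + hi) / 2;
    offer(q, idx_[mid]);
    const double gap = q[d] - coord(idx_[mid], d);
    if (gap < 0) {
      knn_rec(lo, mid, depth + 1, q);
      if (-gap < worst_) knn_rec(mid + 1, hi, depth + 1, q);
    } else {
      knn_rec(mid + 1, hi, depth + 1, q);
      if (gap < worst_) knn_rec(lo, mid, depth + 1, q);
    }
  }

  inline void offer(const double* q, int i) const {
    if (i == self_) return;
    const double dd = dist(q, i, worst_);
    if (dd >= worst_) return;
    if (static_cast<int>(heap_.size()) < k_) {
      heap_.push_back(dd);
      std::push_heap(heap_.begin(), heap_.end());
      if (static_cast<int>(heap_.size()) == k_) worst_ = heap_.front();
    } else {
      std::pop_heap(heap_.begin(), heap_.end());
      heap_.back() = dd;
      std::push_heap(heap_.begin(), heap_.end());
      worst_ = heap_.front();
    }
  }

  void count_rec(int lo, int hi, int depth, const double* q, int self,
                 double eps, int& cnt) const {
    if (hi - lo <= LEAF) {
      for (int p = lo; p < hi; ++p) {
        const int i = idx_[p];
        if (i != self && dist(q, i, eps) < eps) ++cnt;
      }
      return;
    }
    const int d = depth % dim_;
    const int mid = (lo + hi) / 2;
    const int im = idx_[mid];
    if (im != self && dist(q, im, eps) < eps) ++cnt;
    const double gap = q[d] - coord(im, d);
    if (gap < 0) {
      count_rec(lo, mid, depth + 1, q, self, eps, cnt);
      if (-gap < eps) count_rec(mid + 1, hi, depth + 1, q, self, eps, cnt);
    } else {
      count_rec(mid + 1, hi, depth + 1, q, self, eps, cnt);
      if (gap < eps) count_rec(lo, mid, depth + 1, q, self, eps, cnt);
    }
  }

  static const int LEAF = 8;
};

}  // namespace

// [[Rcpp::export]]
List cpp_knn_mi(const NumericMatrix& x, const NumericMatrix& y, int k) {
  const int n = x.nrow(), dx = x.ncol(), dy = y.ncol();
  if (y.nrow() != n) stop("x and y must have the same number of samples");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k <= n - 1");

  // row-major copies (joint and marginals)
  std::vector<double> jp(static_cast<size_t>(n) * (dx + dy));
  std::vector<double> xp(static_cast<size_t>(n) * dx);
  std::vector<double> yp(static_cast<size_t>(n) * dy);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dx; ++c) {
      jp[i * (dx + dy) + c] = x(i, c);
      xp[i * dx + c] = x(i, c);
    }
    for (int c = 0; c < dy; ++c) {
      jp[i * (dx + dy) + dx + c] = y(i, c);
      yp[i * dy + c] = y(i, c);
    }
  }

  KDTree jt, xt, yt;
  jt.build(jp, n, dx + dy);
  xt.build(xp, n, dx);
  yt.build(yp, n, dy);

  std::vector<double> eps(n);
  int ties = 0;
  for (int i = 0; i < n; ++i) {
    eps[i] = jt.knn_dist(&jp[i * (dx + dy)], i, k);
    if (eps[i] <= 0.0) ++ties;
  }
  if (ties > 0) return List::create(_["mi"] = NA_REAL, _["duplicates"] = ties);

  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const int nx = xt.count_within(&xp[i * dx], i, eps[i]);
    const int ny = yt.count_within(&yp[i * dy], i, eps[i]);
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  const double mi =
      R::digamma(static_cast<double>(k)) + R::digamma(static_cast<double>(n)) -
      acc / n;
  return List::create(_["mi"] = mi, _["duplicates"] = 0);
}
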