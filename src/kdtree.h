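#ifndef HERD3D_KDTREE_H
#define HERD3D_KDTREE_H

#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
#include "geom.h"

namespace herd3d {

// Static 3D kd-tree over a flat point array (n x 3, row-major).
// knn keeps the best-k in a small sorted array (k is always small here),
// which beats a heap for the query sizes this package uses.
class KDTree {
 public:
  KDTree(const double* pts, int n) : pts_(pts), n_(n) {
    ids_.resize(n_);
    for (int i = 0; i < n_; ++i) ids_[i] = i;
    nodes_.reserve(n_);
    root_ = n_ > 0 ? build(0, n_, 0) : -1;
  }

  // k nearest neighbours; fills idx (0-based) and squared distances
  // (ascending), returns count.
  int knn(const Vec3& q, int k, int* idx, double* d2) const {
    Best b;
    b.k = k;
    b.count = 0;
    b.idx = idx;
    b.d2 = d2;
    if (root_ >= 0) search(root_, q, b);
    return b.count;
  }

  double nn_dist2(const Vec3& q) const {
    int i;
    double d2;
    if (knn(q, 1, &i, &d2) == 0) return std::numeric_limits<double>::infinity();
    return d2;
  }

 private:
  struct Node { int pt, dim, l, r; double split; };

  struct Best {
    int k, count;
    int* idx;
    double* d2;
    double worst() const {
      return count < k ? std::numeric_limits<double>::infinity() : d2[count - 1];
    }
    void insert(double d, int i) {
      if (count == k && d >= d2[count - 1]) return;
      int pos = count < k ? count : k - 1;
      while (pos > 0 && d2[pos - 1] > d) {
        d2[pos] = d2[pos - 1];
        idx[pos] = idx[pos - 1];
        --pos;
      }
      d2[pos] = d;
      idx[pos] = i;
      if (count < k) ++count;
    }
  };

  int build(int lo, int hi, int depth) {
    int dim = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(ids_.begin() + lo, ids_.begin() + mid, ids_.begin() + hi,
                     [&](int a, int b) { return pts_[3 * a + dim] < pts_[3 * b + dim]; });
    Node nd;
    nd.pt = ids_[mid];
    nd.dim = dim;
    nd.split = pts_[3 * nd.pt + dim];
    int self = (int)nodes_.size();
    nodes_.push_back(nd);
    nodes_[self].l = (mid > lo) ? build(lo, mid, depth + 1) : -1;
    nodes_[self].r = (mid + 1 < hi) ? build(mid + 1, hi, depth + 1) : -1;
    return self;
  }

  void search(int ni, const Vec3& q, Best& b) const {
    const Node& nd = nodes_[ni];
    const double* p = pts_ + 3 * nd.pt;
    double dx = q.x - p[0], dy = q.y - p[1], dz = q.z - p[2];
    b.insert(dx * dx + dy * dy + dz * dz, nd.pt);
    double diff = q[nd.dim] - nd.split;
    int near = diff <= 0 ? nd.l : nd.r;
    int far = diff <= 0 ? nd.r : nd.l;
    if (near >= 0) search(near, q, b);
    if (far >= 0 && diff * diff < b.worst()) search(far, q, b);
  }

  const double* pts_;
  int n_, root_;
  std::vector<int> ids_;
  std::vector<Node> nodes_;
};

}  // namespace herd3d

#endif
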