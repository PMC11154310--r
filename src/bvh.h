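#ifndef HERD3D_BVH_H
#define HERD3D_BVH_H

#include <vector>
#include <limits>
#include <algorithm>
#include "geom.h"

namespace herd3d {

// Axis-aligned bounding-box tree over triangles, for closest-point and
// first-hit ray queries against a triangle mesh.
class TriBVH {
 public:
  // V: nv x 3 row-major vertices; F: nt x 3 row-major 0-based triangle indices.
  TriBVH(const double* V, int nv, const int* F, int nt) : V_(V), F_(F), nt_(nt) {
    (void)nv;
    tris_.resize(nt_);
    cent_.resize(3 * nt_);
    for (int t = 0; t < nt_; ++t) {
      tris_[t] = t;
      Vec3 a = vert(F_[3 * t]), b = vert(F_[3 * t + 1]), c = vert(F_[3 * t + 2]);
      cent_[3 * t] = (a.x + b.x + c.x) / 3.0;
      cent_[3 * t + 1] = (a.y + b.y + c.y) / 3.0;
      cent_[3 * t + 2] = (a.z + b.z + c.z) / 3.0;
    }
    if (nt_ > 0) build(0, nt_);
  }

  bool empty() const { return nt_ == 0; }

  // Closest point on the mesh: returns squared distance, closest point, triangle.
  double closest(const Vec3& q, Vec3& cp, int& tri) const {
    double best = std::numeric_limits<double>::infinity();
    tri = -1;
    closest_rec(0, q, best, cp, tri);
    return best;
  }

  // First ray hit: returns t (>0) and triangle index, or t = -1.
  double raycast(const Vec3& o, const Vec3& d, int& tri) const {
    double best = std::numeric_limits<double>::infinity();
    tri = -1;
    Vec3 inv(1.0 / d.x, 1.0 / d.y, 1.0 / d.z);
    ray_rec(0, o, d, inv, best, tri);
    return tri >= 0 ? best : -1.0;
  }

 private:
  struct Node {
    double lo[3], hi[3];
    int l, r, start, count;  // leaf iff count > 0
  };

  Vec3 vert(int i) const { return Vec3(V_[3 * i], V_[3 * i + 1], V_[3 * i + 2]); }

  int build(int lo, int hi) {
    int self = (int)nodes_.size();
    nodes_.push_back(Node());
    Node& nd = nodes_[self];
    for (int k = 0; k < 3; ++k) {
      nd.lo[k] = std::numeric_limits<double>::infinity();
      nd.hi[k] = -std::numeric_limits<double>::infinity();
    }
    for (int i = lo; i < hi; ++i) {
      int t = tris_[i];
      for (int v = 0; v < 3; ++v) {
        const double* p = V_ + 3 * F_[3 * t + v];
        for (int k = 0; k < 3; ++k) {
          nd.lo[k] = std::min(nd.lo[k], p[k]);
          nd.hi[k] = std::max(nd.hi[k], p[k]);
        }
      }
    }
    if (hi - lo <= 4) {
      nd.l = nd.r = -1;
      nd.start = lo;
      nd.count = hi - lo;
      return self;
    }
    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int k = 1; k < 3; ++k)
      if (nd.hi[k] - nd.lo[k] > ext) { ext = nd.hi[k] - nd.lo[k]; axis = k; }
    int mid = (lo + hi) / 2;
    std::nth_element(tris_.begin() + lo, tris_.begin() + mid, tris_.begin() + hi,
                     [&](int a, int b) { return cent_[3 * a + axis] < cent_[3 * b + axis]; });
    nodes_[self].start = -1;
    nodes_[self].count = 0;
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes_[self].l = l;
    nodes_[self].r = r;
    return self;
  }

  double box_dist2(const Node& nd, const Vec3& q) const {
    double d2 = 0;
    for (int k = 0; k < 3; ++k) {
      double v = q[k];
      if (v < nd.lo[k]) d2 += (nd.lo[k] - v) * (nd.lo[k] - v);
      else if (v > nd.hi[k]) d2 += (v - nd.hi[k]) * (v - nd.hi[k]);
    }
    return d2;
  }

  void closest_rec(int ni, const Vec3& q, double& best, Vec3& cp, int& tri) const {
    const Node& nd = nodes_[ni];
    if (nd.count > 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = tris_[i];
        Vec3 c = closest_point_triangle(q, vert(F_[3 * t]), vert(F_[3 * t + 1]),
                                        vert(F_[3 * t + 2]));
        double d2 = norm2(q - c);
        if (d2 < best) { best = d2; cp = c; tri = t; }
      }
      return;
    }
    double dl = box_dist2(nodes_[nd.l], q), dr = box_dist2(nodes_[nd.r], q);
    int first = dl <= dr ? nd.l : nd.r;
    int second = dl <= dr ? nd.r : nd.l;
    double dfirst = std::min(dl, dr), dsecond = std::max(dl, dr);
    if (dfirst < best) closest_rec(first, q, best, cp, tri);
    if (dsecond < best) closest_rec(second, q, best, cp, tri);
  }

  bool box_hit(const Node& nd, const Vec3& o, const Vec3& inv, double tmax) const {
    double t0 = 0, t1 = tmax;
    for (int k = 0; k < 3; ++k) {
      double ta = (nd.lo[k] - o[k]) * inv[k];
      double tb = (nd.hi[k] - o[k]) * inv[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1) return false;
    }
    return true;
  }

  void ray_rec(int ni, const Vec3& o, const Vec3& d, const Vec3& inv,
               double& best, int& tri) const {
    const Node& nd = nodes_[ni];
    if (!box_hit(nd, o, inv, best)) return;
    if (nd.count > 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = tris_[i];
        double hit = ray_triangle(o, d, vert(F_[3 * t]), vert(F_[3 * t + 1]),
                                  vert(F_[3 * t + 2]));
        if (hit > 0 && hit < best) { best = hit; tri = t; }
      }
      return;
    }
    ray_rec(nd.l, o, d, inv, best, tri);
    ray_rec(nd.r, o, d, inv, best, tri);
  }

  const double* V_;
  const int* F_;
  int nt_;
  std::vector<int> tris_;
  std::vector<double> cent_;
  std::vector<Node> nodes_;
};

}  // namespace herd3d

#endif
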