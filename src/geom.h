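#ifndef HERD3D_GEOM_H
#define HERD3D_GEOM_H

#include <cmath>
#include <algorithm>

namespace herd3d {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double& operator[](int i) { return i == 0 ? x : (i == 1 ? y : z); }
  double operator[](int i) const { return i == 0 ? x : (i == 1 ? y : z); }
};

inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const Vec3& a) { return dot(a, a); }
inline double norm(const Vec3& a) { return std::sqrt(norm2(a)); }

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
inline Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { double v = d1 / (d1 - d3); return a + ab * v; }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { double w = d2 / (d2 - d6); return a + ac * w; }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// Moller-Trumbore ray/triangle intersection; returns t >= 0 or -1.
inline double ray_triangle(const Vec3& o, const Vec3& d,
                           const Vec3& a, const Vec3& b, const Vec3& c) {
  const double eps = 1e-12;
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 pv = cross(d, e2);
  double det = dot(e1, pv);
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = o - a;
  double u = dot(tv, pv) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return -1.0;
  Vec3 qv = cross(tv, e1);
  double v = dot(d, qv) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return -1.0;
  double t = dot(e2, qv) * inv;
  return t > 1e-9 ? t : -1.0;
}

}  // namespace herd3d

#endif
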