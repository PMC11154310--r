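#ifndef HERD3D_MARCH_H
#define HERD3D_MARCH_H

#include <vector>
#include <unordered_map>
#include <cstdint>
#include "geom.h"

namespace herd3d {

// Accumulates a welded triangle mesh from marching-tetrahedra cell visits.
// Lattice corners carry globally unique 64-bit keys so shared iso-vertices on
// cell edges are emitted once, making the extracted surface crack-free.
class MarchAccum {
 public:
  std::vector<double> V;  // row-major x,y,z
  std::vector<int> F;     // row-major 0-based triples

  MarchAccum() { edge_map_.reserve(1 << 20); }

  int edge_vertex(uint64_t ka, const Vec3& pa, double va,
                  uint64_t kb, const Vec3& pb, double vb) {
    uint64_t key;
    if (ka < kb) key = (ka << 32) | kb;
    else key = (kb << 32) | ka;
    std::unordered_map<uint64_t, int>::iterator it = edge_map_.find(key);
    if (it != edge_map_.end()) return it->second;
    double t = va / (va - vb);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    Vec3 p = pa + (pb - pa) * t;
    int id = (int)(V.size() / 3);
    V.push_back(p.x);
    V.push_back(p.y);
    V.push_back(p.z);
    edge_map_[key] = id;
    return id;
  }

  void add_tri(int a, int b, int c, const Vec3& ref_dir) {
    if (a == b || b == c || a == c) return;
    Vec3 pa(V[3 * a], V[3 * a + 1], V[3 * a + 2]);
    Vec3 pb(V[3 * b], V[3 * b + 1], V[3 * b + 2]);
    Vec3 pc(V[3 * c], V[3 * c + 1], V[3 * c + 2]);
    Vec3 n = cross(pb - pa, pc - pa);
    if (dot(n, ref_dir) < 0) std::swap(b, c);
    F.push_back(a);
    F.push_back(b);
    F.push_back(c);
  }

 private:
  std::unordered_map<uint64_t, int> edge_map_;
};

// Kuhn 6-tetrahedra decomposition of the unit cube (corner bits x + 2y + 4z).
// All tets share the 0-7 diagonal; face diagonals match across neighbouring
// cells, so the decomposition is globally consistent.
static const int KUHN_TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

inline void march_tet(MarchAccum& acc, const uint64_t key[4], const Vec3 pos[4],
                      const double val[4]) {
  int neg[4], pos_i[4], nn = 0, np = 0;
  for (int i = 0; i < 4; ++i) {
    if (val[i] < 0) neg[nn++] = i;
    else pos_i[np++] = i;
  }
  if (nn == 0 || nn == 4) return;
  Vec3 cn(0, 0, 0), cp(0, 0, 0);
  for (int i = 0; i < nn; ++i) cn = cn + pos[neg[i]] * (1.0 / nn);
  for (int i = 0; i < np; ++i) cp = cp + pos[pos_i[i]] * (1.0 / np);
  Vec3 ref = cp - cn;  // triangles oriented toward the positive (outside) side
  if (nn == 1 || nn == 3) {
    int apex = (nn == 1) ? neg[0] : pos_i[0];
    const int* other = (nn == 1) ? pos_i : neg;
    int e[3];
    for (int i = 0; i < 3; ++i)
      e[i] = acc.edge_vertex(key[apex], pos[apex], val[apex],
                             key[other[i]], pos[other[i]], val[other[i]]);
    acc.add_tri(e[0], e[1], e[2], ref);
  } else {  // nn == 2: quad split into two triangles
    int i = neg[0], j = neg[1], k = pos_i[0], l = pos_i[1];
    int eik = acc.edge_vertex(key[i], pos[i], val[i], key[k], pos[k], val[k]);
    int eil = acc.edge_vertex(key[i], pos[i], val[i], key[l], pos[l], val[l]);
    int ejk = acc.edge_vertex(key[j], pos[j], val[j], key[k], pos[k], val[k]);
    int ejl = acc.edge_vertex(key[j], pos[j], val[j], key[l], pos[l], val[l]);
    acc.add_tri(eik, eil, ejl, ref);
    acc.add_tri(eik, ejl, ejk, ref);
  }
}

inline void march_cell(MarchAccum& acc, const uint64_t key[8], const Vec3 pos[8],
                       const double val[8]) {
  for (int t = 0; t < 6; ++t) {
    uint64_t k[4];
    Vec3 p[4];
    double v[4];
    for (int i = 0; i < 4; ++i) {
      int c = KUHN_TETS[t][i];
      k[i] = key[c];
      p[i] = pos[c];
      v[i] = val[c];
    }
    march_tet(acc, k, p, v);
  }
}

}  // namespace herd3d

#endif
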