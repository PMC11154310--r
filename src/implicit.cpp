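#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <cstdint>
#include "geom.h"
#include "kdtree.h"
#include "march.h"

using namespace Rcpp;
using namespace herd3d;

static std::vector<double> row_major(const NumericMatrix& m) {
  std::vector<double> out((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[(size_t)i * m.ncol() + j] = m(i, j);
  return out;
}

static List mesh_result(const MarchAccum& acc) {
  int nv = (int)(acc.V.size() / 3), nf = (int)(acc.F.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = acc.V[3 * i + j];
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = acc.F[3 * i + j] + 1;  // 1-based for R
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

static inline double nudge(double v) { return v == 0 ? 1e-300 : v; }

// Extract the zero level set of a field sampled on a full lattice of
// (n1 x n2 x n3) nodes with spacing `cell` and origin `origin`.
// [[Rcpp::export]]
List cpp_march_field(NumericVector field, IntegerVector dims,
                     NumericVector origin, double cell) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if ((R_xlen_t)n1 * n2 * n3 != field.size()) stop("field size does not match dims");
  MarchAccum acc;
  uint64_t NX = (uint64_t)n1, NXY = (uint64_t)n1 * n2;
  Vec3 org(origin[0], origin[1], origin[2]);
  uint64_t key[8];
  Vec3 pos[8];
  double val[8];
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          key[c] = (uint64_t)ci + NX * cj + NXY * ck;
          pos[c] = Vec3(org.x + ci * cell, org.y + cj * cell, org.z + ck * cell);
          val[c] = nudge(field[ci + (R_xlen_t)n1 * (cj + (R_xlen_t)n2 * ck)]);
          if (val[c] < 0) any_neg = true; else any_pos = true;
        }
        if (any_neg && any_pos) march_cell(acc, key, pos, val);
      }
  return mesh_result(acc);
}

namespace {

struct VSplat { double w, x, y, z, f; };

// Separable Chebyshev (cube) dilation of a binary cell mask by r cells.
void dilate_axis(std::vector<uint8_t>& mask, int nx, int ny, int nz, int axis, int r) {
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<int> cum(len + 1);
  std::vector<uint8_t> line(len);
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int b = 0; b < n[o2]; ++b)
    for (int a = 0; a < n[o1]; ++a) {
      size_t base = stride[o1] * a + stride[o2] * b;
      cum[0] = 0;
      for (int i = 0; i < len; ++i)
        cum[i + 1] = cum[i] + (mask[base + stride[axis] * i] ? 1 : 0);
      if (cum[len] == 0) continue;
      for (int i = 0; i < len; ++i) {
        int lo = i - r < 0 ? 0 : i - r;
        int hi = i + r + 1 > len ? len : i + r + 1;
        line[i] = (cum[hi] - cum[lo]) > 0 ? 1 : 0;
      }
      for (int i = 0; i < len; ++i) mask[base + stride[axis] * i] = line[i];
    }
}

}  // namespace

// Indicator-based surface reconstruction from oriented points (the Poisson
// formulation on a narrow band). Unit normals are splatted onto lattice
// nodes with a compact Wendland kernel; the smoothed indicator chi (1
// inside, 0 outside) solves the Poisson equation  lap chi = -div n  with a
// 7-point stencil on all nodes within `band` of the data, with Dirichlet
// boundary values from the nearest point's tangent-plane side, by warm-
// started conjugate gradients. The surface is the chi = 1/2 level set,
// polygonized by marching tetrahedra. Because the indicator accumulates
// across sheets, several misaligned sheets of the same surface yield a
// single consensus surface between them -- the property the interleaved
// pose optimizer relies on -- while well-aligned data is reconstructed at
// full grid resolution.
// [[Rcpp::export]]
List cpp_reconstruct(NumericMatrix points, NumericMatrix normals,
                     double cell, double band, double splat_radius,
                     int cg_max_iter, double cg_tol) {
  int n = points.nrow();
  if (n < 4) stop("too few points");
  if (normals.nrow() != n) stop("points/normals mismatch");
  std::vector<double> P = row_major(points), N = row_major(normals);
  KDTree kd(P.data(), n);
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(lo[j], P[3 * i + j]);
      hi[j] = std::max(hi[j], P[3 * i + j]);
    }
  int rb = (int)std::ceil(band / cell);
  double margin = (rb + 2) * cell;
  // snap the lattice to multiples of the cell so repeated reconstructions
  // of slowly-moving data see a stable grid
  Vec3 org(cell * std::floor((lo[0] - margin) / cell),
           cell * std::floor((lo[1] - margin) / cell),
           cell * std::floor((lo[2] - margin) / cell));
  int nx = (int)std::ceil((hi[0] + margin - org.x) / cell) + 1;
  int ny = (int)std::ceil((hi[1] + margin - org.y) / cell) + 1;
  int nz = (int)std::ceil((hi[2] + margin - org.z) / cell) + 1;
  if ((double)nx * ny * nz > 4e8) stop("reconstruction grid too large; lower depth");

  // band mask over cells
  std::vector<uint8_t> cmask((size_t)nx * ny * nz, 0);
  for (int i = 0; i < n; ++i) {
    int ci = (int)std::floor((P[3 * i] - org.x) / cell);
    int cj = (int)std::floor((P[3 * i + 1] - org.y) / cell);
    int ck = (int)std::floor((P[3 * i + 2] - org.z) / cell);
    if (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 && ck < nz)
      cmask[(size_t)ci + (size_t)nx * cj + (size_t)nx * ny * ck] = 1;
  }
  dilate_axis(cmask, nx, ny, nz, 0, rb);
  dilate_axis(cmask, nx, ny, nz, 1, rb);
  dilate_axis(cmask, nx, ny, nz, 2, rb);

  // node classification: a node is in-band if it touches a band cell
  int mx = nx + 1, my = ny + 1, mz = nz + 1;
  size_t nnodes = (size_t)mx * my * mz;
  // status: -1 outside band; -(2+k) Dirichlet k; >=0 unknown index
  std::vector<int> status(nnodes, -1);
  size_t sx = 1, sy = (size_t)mx, sz = (size_t)mx * my;
  std::vector<int64_t> inband;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t crow = (size_t)nx * j + (size_t)nx * ny * k;
      for (int i = 0; i < nx; ++i) {
        if (!cmask[crow + i]) continue;
        for (int c = 0; c < 8; ++c) {
          size_t node = (size_t)(i + (c & 1)) * sx + (size_t)(j + ((c >> 1) & 1)) * sy +
                        (size_t)(k + ((c >> 2) & 1)) * sz;
          if (status[node] == -1) { status[node] = -2; inband.push_back((int64_t)node); }
        }
      }
    }

  // split into Dirichlet boundary (any 6-neighbour outside band) and unknowns
  std::vector<int64_t> unknown_nodes, dirichlet_nodes;
  for (size_t t = 0; t < inband.size(); ++t) {
    int64_t node = inband[t];
    int k = (int)(node / (int64_t)sz);
    int j = (int)((node - (int64_t)k * sz) / (int64_t)sy);
    int i = (int)(node - (int64_t)k * sz - (int64_t)j * sy);
    bool edge = (i == 0 || i == mx - 1 || j == 0 || j == my - 1 || k == 0 || k == mz - 1);
    if (!edge) {
      edge = status[node - sx] == -1 || status[node + sx] == -1 ||
             status[node - sy] == -1 || status[node + sy] == -1 ||
             status[node - sz] == -1 || status[node + sz] == -1;
    }
    if (edge) dirichlet_nodes.push_back(node);
    else unknown_nodes.push_back(node);
  }
  std::vector<double> dval(dirichlet_nodes.size());
  for (size_t t = 0; t < dirichlet_nodes.size(); ++t) {
    int64_t node = dirichlet_nodes[t];
    int k = (int)(node / (int64_t)sz);
    int j = (int)((node - (int64_t)k * sz) / (int64_t)sy);
    int i = (int)(node - (int64_t)k * sz - (int64_t)j * sy);
    Vec3 x(org.x + i * cell, org.y + j * cell, org.z + k * cell);
    int idx1;
    double d21;
    kd.knn(x, 1, &idx1, &d21);
    const double* p = P.data() + 3 * idx1;
    const double* nv = N.data() + 3 * idx1;
    double f = nv[0] * (x.x - p[0]) + nv[1] * (x.y - p[1]) + nv[2] * (x.z - p[2]);
    dval[t] = f < 0 ? 1.0 : 0.0;  // indicator: 1 inside, 0 outside
    status[node] = -2 - (int)t;
  }
  int nun = (int)unknown_nodes.size();
  for (int t = 0; t < nun; ++t) status[unknown_nodes[t]] = t;

  // splat normalized normals (and plane distances for the warm start)
  std::unordered_map<int64_t, VSplat> vfield;
  vfield.reserve((size_t)n * 8);
  double R = splat_radius * cell;
  int rc = (int)std::ceil(R / cell);
  for (int i = 0; i < n; ++i) {
    const double* p = P.data() + 3 * i;
    const double* nv = N.data() + 3 * i;
    int ci = (int)std::floor((p[0] - org.x) / cell);
    int cj = (int)std::floor((p[1] - org.y) / cell);
    int ck = (int)std::floor((p[2] - org.z) / cell);
    for (int dz = -rc; dz <= rc + 1; ++dz)
      for (int dy = -rc; dy <= rc + 1; ++dy)
        for (int dx = -rc; dx <= rc + 1; ++dx) {
          int ix = ci + dx, iy = cj + dy, iz = ck + dz;
          if (ix < 0 || ix >= mx || iy < 0 || iy >= my || iz < 0 || iz >= mz) continue;
          double x = org.x + ix * cell, y = org.y + iy * cell, z = org.z + iz * cell;
          double ddx = x - p[0], ddy = y - p[1], ddz = z - p[2];
          double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (r2 >= R * R) continue;
          double r = std::sqrt(r2) / R;
          double w = (1 - r) * (1 - r) * (1 - r) * (1 - r) * (4 * r + 1);
          VSplat& s = vfield[(int64_t)ix * sx + (int64_t)iy * sy + (int64_t)iz * sz];
          s.w += w;
          s.x += w * nv[0];
          s.y += w * nv[1];
          s.z += w * nv[2];
          s.f += w * (nv[0] * ddx + nv[1] * ddy + nv[2] * ddz);
        }
  }
  // normalized direction at a node (zero where unsupported)
  const double wmin = 1e-9;
  struct Dir {
    const std::unordered_map<int64_t, VSplat>& vf;
    double axis(int64_t node, int a) const {
      std::unordered_map<int64_t, VSplat>::const_iterator it = vf.find(node);
      if (it == vf.end() || it->second.w < 1e-9) return 0.0;
      const VSplat& s = it->second;
      double len = std::sqrt(s.x * s.x + s.y * s.y + s.z * s.z);
      if (len < 1e-12) return 0.0;
      return (a == 0 ? s.x : (a == 1 ? s.y : s.z)) / len;
    }
  } dir = {vfield};

  // right-hand side b = -div(n) (central differences), Dirichlet terms added
  std::vector<double> b(nun, 0.0), x0(nun, -1.0);
  std::vector<int> nb((size_t)nun * 6);
  size_t step[6] = {sx, sx, sy, sy, sz, sz};
  for (int t = 0; t < nun; ++t) {
    int64_t node = unknown_nodes[t];
    double div = 0;
    div += (dir.axis(node + sx, 0) - dir.axis(node - sx, 0)) / 2;
    div += (dir.axis(node + sy, 1) - dir.axis(node - sy, 1)) / 2;
    div += (dir.axis(node + sz, 2) - dir.axis(node - sz, 2)) / 2;
    double rhs = div;  // (6 chi_i - sum chi_nb) = +div n
    int64_t nbr[6] = {node - (int64_t)sx, node + (int64_t)sx, node - (int64_t)sy,
                      node + (int64_t)sy, node - (int64_t)sz, node + (int64_t)sz};
    (void)step;
    for (int a = 0; a < 6; ++a) {
      int st = status[nbr[a]];
      if (st >= 0) nb[(size_t)t * 6 + a] = st;
      else {  // Dirichlet neighbour: move to rhs
        nb[(size_t)t * 6 + a] = -1;
        rhs += dval[-(st + 2)];
      }
    }
    b[t] = rhs;
    std::unordered_map<int64_t, VSplat>::const_iterator it = vfield.find(node);
    if (it != vfield.end() && it->second.w >= wmin)
      x0[t] = it->second.f / it->second.w < 0 ? 1.0 : 0.0;
  }

  // warm start: nodes without local plane support copy a neighbour (BFS)
  {
    std::deque<int> q;
    for (int t = 0; t < nun; ++t)
      if (x0[t] >= 0) q.push_back(t);
    if (q.empty()) { for (int t = 0; t < nun; ++t) x0[t] = 0.5; }
    else {
      while (!q.empty()) {
        int t = q.front();
        q.pop_front();
        for (int a = 0; a < 6; ++a) {
          int u = nb[(size_t)t * 6 + a];
          if (u >= 0 && x0[u] < 0) { x0[u] = x0[t]; q.push_back(u); }
        }
      }
      for (int t = 0; t < nun; ++t) if (x0[t] < 0) x0[t] = 0.5;
    }
  }

  // conjugate gradients on A chi = b, A = 6 I - adjacency (SPD)
  std::vector<double> x(x0), r(nun), p(nun), Ap(nun);
  double bnorm = 0;
  for (int t = 0; t < nun; ++t) bnorm += b[t] * b[t];
  bnorm = std::sqrt(std::max(bnorm, 1e-30));
  for (int t = 0; t < nun; ++t) {
    double ax = 6 * x[t];
    const int* nbt = &nb[(size_t)t * 6];
    for (int a = 0; a < 6; ++a) if (nbt[a] >= 0) ax -= x[nbt[a]];
    r[t] = b[t] - ax;
  }
  p = r;
  double rs = 0;
  for (int t = 0; t < nun; ++t) rs += r[t] * r[t];
  for (int it = 0; it < cg_max_iter && std::sqrt(rs) > cg_tol * bnorm; ++it) {
    for (int t = 0; t < nun; ++t) {
      double ap = 6 * p[t];
      const int* nbt = &nb[(size_t)t * 6];
      for (int a = 0; a < 6; ++a) if (nbt[a] >= 0) ap -= p[nbt[a]];
      Ap[t] = ap;
    }
    double pAp = 0;
    for (int t = 0; t < nun; ++t) pAp += p[t] * Ap[t];
    if (pAp <= 0) break;
    double alpha = rs / pAp;
    double rs_new = 0;
    for (int t = 0; t < nun; ++t) {
      x[t] += alpha * p[t];
      r[t] -= alpha * Ap[t];
      rs_new += r[t] * r[t];
    }
    double beta = rs_new / rs;
    rs = rs_new;
    for (int t = 0; t < nun; ++t) p[t] = r[t] + beta * p[t];
  }

  // isovalue calibration: the level passing through the data is the mean
  // indicator value at the sample points (trilinear interpolation), the
  // standard choice for indicator-based reconstruction; it cancels the
  // outward bias the curvature term of the normal field would otherwise
  // give the 1/2 level on curved surfaces
  double iso = 0.5;
  {
    double acc_chi = 0;
    R_xlen_t cnt = 0;
    for (int i = 0; i < n; ++i) {
      double gx = (P[3 * i] - org.x) / cell;
      double gy = (P[3 * i + 1] - org.y) / cell;
      double gz = (P[3 * i + 2] - org.z) / cell;
      int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
      if (ix < 0 || ix >= mx - 1 || iy < 0 || iy >= my - 1 || iz < 0 || iz >= mz - 1)
        continue;
      double fx = gx - ix, fy = gy - iy, fz = gz - iz;
      double chi = 0;
      bool ok = true;
      for (int c = 0; c < 8 && ok; ++c) {
        int jx = ix + (c & 1), jy = iy + ((c >> 1) & 1), jz = iz + ((c >> 2) & 1);
        int st = status[(int64_t)jx * sx + (int64_t)jy * sy + (int64_t)jz * sz];
        double v;
        if (st >= 0) v = x[st];
        else if (st <= -2) v = dval[-(st + 2)];
        else { ok = false; break; }
        double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
                   (((c >> 2) & 1) ? fz : 1 - fz);
        chi += w * v;
      }
      if (ok) { acc_chi += chi; ++cnt; }
    }
    if (cnt > 0) iso = acc_chi / cnt;
  }

  // march chi = iso over band cells (f = iso - chi: negative inside)
  MarchAccum acc;
  uint64_t key[8];
  Vec3 pos[8];
  double val[8];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t crow = (size_t)nx * j + (size_t)nx * ny * k;
      for (int i = 0; i < nx; ++i) {
        if (!cmask[crow + i]) continue;
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          int ix = i + (c & 1), iy = j + ((c >> 1) & 1), iz = k + ((c >> 2) & 1);
          int64_t node = (int64_t)ix * sx + (int64_t)iy * sy + (int64_t)iz * sz;
          int st = status[node];
          double chi = st >= 0 ? x[st] : dval[-(st + 2)];
          key[c] = (uint64_t)node;
          pos[c] = Vec3(org.x + ix * cell, org.y + iy * cell, org.z + iz * cell);
          val[c] = nudge(iso - chi);
          if (val[c] < 0) any_neg = true; else any_pos = true;
        }
        if (any_neg && any_pos) march_cell(acc, key, pos, val);
      }
    }
  return mesh_result(acc);
}
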