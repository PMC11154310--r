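#include <Rcpp.h>
#include "geom.h"
#include "kdtree.h"
#include "bvh.h"

using namespace Rcpp;
using namespace herd3d;

static std::vector<double> row_major_d(const NumericMatrix& m) {
  std::vector<double> out((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[(size_t)i * m.ncol() + j] = m(i, j);
  return out;
}

static std::vector<int> row_major_i0(const IntegerMatrix& m) {
  // 1-based R indices to 0-based
  std::vector<int> out((size_t)m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      out[(size_t)i * m.ncol() + j] = m(i, j) - 1;
  return out;
}

// k nearest neighbours of each query row among the reference rows.
// Returns 1-based indices and Euclidean distances (query x k).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  int n = ref.nrow(), m = query.nrow();
  if (n == 0) stop("empty reference set");
  if (k < 1) stop("k must be >= 1");
  k = std::min(k, n);
  std::vector<double> R = row_major_d(ref);
  KDTree kd(R.data(), n);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<int> ii(k);
  std::vector<double> dd(k);
  for (int i = 0; i < m; ++i) {
    Vec3 q(query(i, 0), query(i, 1), query(i, 2));
    int got = kd.knn(q, k, ii.data(), dd.data());
    for (int j = 0; j < got; ++j) {
      idx(i, j) = ii[j] + 1;
      dist(i, j) = std::sqrt(dd[j]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// TRUE for each query point whose nearest reference point lies within radius.
// [[Rcpp::export]]
LogicalVector cpp_nn_within(NumericMatrix ref, NumericMatrix query, double radius) {
  int n = ref.nrow(), m = query.nrow();
  LogicalVector out(m);
  if (n == 0) { std::fill(out.begin(), out.end(), FALSE); return out; }
  std::vector<double> R = row_major_d(ref);
  KDTree kd(R.data(), n);
  double r2 = radius * radius;
  for (int i = 0; i < m; ++i) {
    Vec3 q(query(i, 0), query(i, 1), query(i, 2));
    out[i] = kd.nn_dist2(q) <= r2;
  }
  return out;
}

// Exact closest point on a triangle mesh for each query point.
// Returns distances, closest points and 1-based triangle indices.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  if (F.nrow() == 0) stop("empty mesh");
  std::vector<double> Vf = row_major_d(V);
  std::vector<int> Ff = row_major_i0(F);
  TriBVH bvh(Vf.data(), V.nrow(), Ff.data(), F.nrow());
  int m = P.nrow();
  NumericVector dist(m);
  NumericMatrix cp(m, 3);
  IntegerVector tri(m);
  for (int i = 0; i < m; ++i) {
    Vec3 q(P(i, 0), P(i, 1), P(i, 2)), c;
    int t;
    double d2 = bvh.closest(q, c, t);
    dist[i] = std::sqrt(d2);
    cp(i, 0) = c.x;
    cp(i, 1) = c.y;
    cp(i, 2) = c.z;
    tri[i] = t + 1;
  }
  return List::create(_["dist"] = dist, _["point"] = cp, _["tri"] = tri);
}

namespace {

// Owns a copy of the mesh plus its BVH so repeated queries against the same
// mesh (the inner loops of the registration) skip rebuilding the tree.
struct MeshHandle {
  std::vector<double> V;
  std::vector<int> F;
  TriBVH* bvh;
  MeshHandle(const NumericMatrix& Vm, const IntegerMatrix& Fm)
      : V(row_major_d(Vm)), F(row_major_i0(Fm)) {
    bvh = new TriBVH(V.data(), Vm.nrow(), F.data(), Fm.nrow());
  }
  ~MeshHandle() { delete bvh; }
};

}  // namespace

// Build a reusable closest-point query structure for a mesh.
// [[Rcpp::export]]
SEXP cpp_mesh_handle(NumericMatrix V, IntegerMatrix F) {
  if (F.nrow() == 0) stop("empty mesh");
  XPtr<MeshHandle> ptr(new MeshHandle(V, F), true);
  return ptr;
}

// Closest point on a prebuilt mesh handle for each query point.
// [[Rcpp::export]]
List cpp_closest_on_handle(SEXP handle, NumericMatrix P) {
  XPtr<MeshHandle> ptr(handle);
  int m = P.nrow();
  NumericVector dist(m);
  NumericMatrix cp(m, 3);
  IntegerVector tri(m);
  for (int i = 0; i < m; ++i) {
    Vec3 q(P(i, 0), P(i, 1), P(i, 2)), c;
    int t;
    double d2 = ptr->bvh->closest(q, c, t);
    dist[i] = std::sqrt(d2);
    cp(i, 0) = c.x;
    cp(i, 1) = c.y;
    cp(i, 2) = c.z;
    tri[i] = t + 1;
  }
  return List::create(_["dist"] = dist, _["point"] = cp, _["tri"] = tri);
}

// First-hit ray casting against a prebuilt mesh handle.
// [[Rcpp::export]]
List cpp_raycast_on_handle(SEXP handle, NumericMatrix origins, NumericMatrix dirs) {
  XPtr<MeshHandle> ptr(handle);
  const TriBVH& bvh = *ptr->bvh;
  int m = origins.nrow();
  NumericVector t(m);
  IntegerVector tri(m);
  for (int i = 0; i < m; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    int tr;
    double hit = bvh.raycast(o, d, tr);
    if (tr >= 0) { t[i] = hit; tri[i] = tr + 1; }
    else { t[i] = NA_REAL; tri[i] = NA_INTEGER; }
  }
  return List::create(_["t"] = t, _["tri"] = tri);
}

// First-hit ray casting against a triangle mesh. Rays that miss get t = NA.
// [[Rcpp::export]]
List cpp_raycast(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                 NumericMatrix dirs) {
  if (F.nrow() == 0) stop("empty mesh");
  std::vector<double> Vf = row_major_d(V);
  std::vector<int> Ff = row_major_i0(F);
  TriBVH bvh(Vf.data(), V.nrow(), Ff.data(), F.nrow());
  int m = origins.nrow();
  NumericVector t(m);
  IntegerVector tri(m);
  for (int i = 0; i < m; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    int tr;
    double hit = bvh.raycast(o, d, tr);
    if (tr >= 0) { t[i] = hit; tri[i] = tr + 1; }
    else { t[i] = NA_REAL; tri[i] = NA_INTEGER; }
  }
  return List::create(_["t"] = t, _["tri"] = tri);
}
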