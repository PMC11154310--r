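# Oriented-point surface reconstruction: the global-mesh stage of the
# interleaved optimizer. The surface is the 1/2 level set of a smoothed
# indicator function (1 inside, 0 outside) obtained by solving the Poisson
# equation for the splatted normal field on a narrow band of grid cells
# around the data. The `depth` parameter plays the same role as an octree
# depth: the grid cell size is the bounding-box extent divided by 2^depth.

#' Oriented point set
#'
#' World-frame points with unit normals, pooled across cameras.
#'
#' @param points n x 3 matrix (meters).
#' @param normals n x 3 matrix of unit normals (checked to 1e-6).
#' @param cloud optional 0-based integer source-cloud (camera) id per point,
#'   carried as provenance metadata.
#' @return An object of class `oriented_points`.
#' @export
oriented_points <- function(points, normals, cloud = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  normals <- matrix(as.numeric(normals), ncol = 3)
  if (nrow(points) != nrow(normals)) stop("equal counts of points and normals required")
  if (is.null(cloud)) cloud <- integer(nrow(points))
  if (length(cloud) != nrow(points)) stop("one cloud id per point required")
  ok <- stats::complete.cases(points) & stats::complete.cases(normals)
  points <- points[ok, , drop = FALSE]
  normals <- normals[ok, , drop = FALSE]
  cloud <- as.integer(cloud[ok])
  len <- sqrt(rowSums(normals^2))
  if (any(len < 1e-8)) stop("degenerate (zero) normals")
  if (any(abs(len - 1) > 1e-6)) normals <- normals / len
  structure(list(points = points, normals = normals, cloud = cloud),
            class = "oriented_points")
}

#' @export
print.oriented_points <- function(x, ...) {
  cat(sprintf("<oriented_points> %d oriented points\n", nrow(x$points)))
  invisible(x)
}

#' Reconstruct a surface from oriented points
#'
#' Poisson-type reconstruction on a narrow band: the unit normals are
#' splatted onto a uniform grid with cell size `extent / 2^depth` (extent =
#' largest bounding-box side), the smoothed indicator function solves the
#' Poisson equation of that normal field on all cells within `band` of the
#' data (conjugate gradients with Dirichlet boundary values from the
#' nearest point's tangent-plane side), and the 1/2 level set is polygonized
#' by marching tetrahedra.
#'
#' Because the indicator accumulates across sheets, data pooled from
#' several roughly-calibrated cameras yields a single consensus surface
#' midway between disagreeing sheets, while well-aligned regions are
#' reconstructed at full grid resolution. Holes up to about the band radius
#' are bridged; the surface never extends past the band, and a
#' low-support fringe can additionally be trimmed. On well-sampled closed
#' shapes the result is watertight.
#'
#' @param pts an [oriented_points()] set (>= 100 points), or a list/mesh
#'   with `points`/`vertices` and `normals`.
#' @param depth resolution exponent, integer in [4, 12]. Depth 8 gives a
#'   smooth intermediate surface; depth 9 resolves more detail.
#' @param band narrow-band radius in meters; default
#'   `max(3 cell, 2.5 x median point spacing)`.
#' @param splat normal-splatting kernel radius in cells (floored at the
#'   point spacing so the dipole layer stays contiguous).
#' @param trim_quantile fraction of worst-supported triangles eligible for
#'   trimming (a triangle is trimmed only if it is also farther from the
#'   data than the band radius, so supported surface is never cut).
#' @param cg_max_iter,cg_tol conjugate-gradient iteration cap and relative
#'   residual tolerance of the Poisson solve.
#' @param cell override the grid cell size in meters (used by the
#'   interleaved optimizer to keep the lattice fixed while poses move).
#' @param normals compute unit vertex normals on the result (skippable for
#'   intermediate meshes where only face normals are used).
#' @return A [tri_mesh()] with vertex normals.
#' @export
reconstruct_surface <- function(pts, depth = 8, band = NULL, splat = 1.5,
                                trim_quantile = 0.01, cg_max_iter = 200,
                                cg_tol = 1e-4, cell = NULL, normals = TRUE) {
  if (!inherits(pts, "oriented_points")) {
    p <- if (!is.null(pts$points)) pts$points else pts$vertices
    pts <- oriented_points(p, pts$normals)
  }
  n <- nrow(pts$points)
  if (n < 100) stop("need at least 100 oriented points (got ", n, ")")
  if (depth < 4 || depth > 12) stop("depth must be in [4, 12]")
  extent <- max(apply(pts$points, 2, function(x) diff(range(x))))
  if (extent <= 0) stop("degenerate point set")
  if (is.null(cell)) cell <- extent / 2^depth
  take <- seq(1, n, length.out = min(n, 2000))
  nn <- cpp_knn(pts$points, pts$points[take, , drop = FALSE], 2)
  spacing <- stats::median(nn$dist[, 2])
  splat <- max(splat, spacing / cell)
  if (is.null(band)) band <- max(3 * cell, 2.5 * spacing)
  res <- cpp_reconstruct(pts$points, pts$normals, cell, band, splat,
                         as.integer(cg_max_iter), cg_tol)
  if (nrow(res$triangles) == 0) stop("reconstruction produced an empty surface")
  mesh <- tri_mesh(res$vertices, res$triangles, validate = FALSE)
  if (trim_quantile > 0) {
    cen <- (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
            mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
            mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
    d <- cpp_knn(pts$points, cen, 1)$dist[, 1]
    thr <- max(stats::quantile(d, 1 - trim_quantile), band)
    if (any(d > thr)) {
      mesh$triangles <- mesh$triangles[d <= thr, , drop = FALSE]
      used <- sort(unique(as.vector(mesh$triangles)))
      mesh <- mesh_subset_vertices(mesh, used)
    }
  }
  if (normals) mesh$normals <- vertex_normals(mesh)
  mesh
}
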