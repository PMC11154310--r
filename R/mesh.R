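# Triangle-mesh container and the mesh primitives the segmentation and
# registration stages are built on. Triangles are counter-clockwise as seen
# from the camera that generated them; vertex normals are unit vectors.

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix of 3D points (meters).
#' @param triangles m x 3 integer matrix of vertex indices (1-based,
#'   counter-clockwise winding).
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @param labels optional per-vertex integer labels (carried through
#'   subsetting; the simulator uses 1 = animal, 0 = environment).
#' @param validate check invariants (indices in range, no duplicate triangle,
#'   normals unit to 1e-6). Internal callers that construct meshes from
#'   already-checked data may skip this.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, normals = NULL, labels = NULL,
                     validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (validate && nrow(triangles) > 0) {
    if (min(triangles) < 1 || max(triangles) > nrow(vertices))
      stop("triangle indices out of range")
    key <- tri_keys(triangles, nrow(vertices))
    if (anyDuplicated(key)) stop("duplicate triangles")
  }
  if (!is.null(normals)) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    if (nrow(normals) != nrow(vertices)) stop("one normal per vertex required")
    if (validate && nrow(normals) > 0) {
      len <- sqrt(rowSums(normals^2))
      if (any(abs(len - 1) > 1e-6)) stop("vertex normals must be unit length (1e-6)")
    }
  }
  if (!is.null(labels) && length(labels) != nrow(vertices))
    stop("one label per vertex required")
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, labels = labels), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles%s%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$normals)) ", with normals" else "",
              if (!is.null(x$labels)) ", with labels" else ""))
  invisible(x)
}

# Order-free key identifying a triangle by its sorted vertex set.
tri_keys <- function(triangles, nv) {
  s <- t(apply(triangles, 1, sort))
  if (nrow(triangles) == 1) s <- matrix(s, ncol = 3)
  (s[, 1] * (nv + 1) + s[, 2]) * (nv + 1) + s[, 3]
}

# Directed edges of all triangles in winding order: (a,b),(b,c),(c,a).
directed_edges <- function(triangles) {
  rbind(triangles[, c(1, 2), drop = FALSE],
        triangles[, c(2, 3), drop = FALSE],
        triangles[, c(3, 1), drop = FALSE])
}

# Undirected edge keys (numeric, collision-free for nv < 3e6).
edge_keys <- function(edges, nv) {
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  lo * (nv + 1) + hi
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return 2-column integer matrix, one row per unique undirected edge.
#' @export
mesh_edges <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(matrix(integer(), ncol = 2))
  e <- directed_edges(mesh$triangles)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(edge_keys(e, nrow(mesh$vertices))), , drop = FALSE]
}

# Count of incident triangles per unique undirected edge.
edge_use_counts <- function(mesh) {
  e <- directed_edges(mesh$triangles)
  key <- edge_keys(e, nrow(mesh$vertices))
  tab <- table(key)
  uniq <- as.numeric(names(tab))
  lo <- floor(uniq / (nrow(mesh$vertices) + 1))
  list(edges = cbind(as.integer(lo), as.integer(uniq - lo * (nrow(mesh$vertices) + 1))),
       count = as.integer(tab))
}

#' Per-triangle unit normals
#'
#' @param mesh a [tri_mesh()].
#' @return m x 3 matrix of unit triangle normals (right-hand rule on the
#'   winding order).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  a <- V[Tm[, 1], , drop = FALSE]
  u <- V[Tm[, 2], , drop = FALSE] - a
  v <- V[Tm[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Vertex normals as the normalized mean of incident triangle normals
#'
#' @param mesh a [tri_mesh()].
#' @param fallback unit vector used for vertices with no incident triangle.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh, fallback = c(0, 0, -1)) {
  n <- matrix(rep(fallback, each = nrow(mesh$vertices)), ncol = 3)
  if (nrow(mesh$triangles) > 0) {
    fn <- face_normals(mesh)
    idx <- as.vector(mesh$triangles)
    acc <- rowsum(rbind(fn, fn, fn), idx)
    touched <- as.integer(rownames(acc))
    len <- sqrt(rowSums(acc^2))
    len[len == 0] <- 1
    n[touched, ] <- acc / len
  }
  n
}

#' Mesh summary statistics
#'
#' @param mesh a [tri_mesh()].
#' @return List with `vertices`, `triangles`, `mean_edge` (meters),
#'   `watertight` (no boundary edge, i.e. every edge in exactly two
#'   triangles) and `euler` (V - E + F).
#' @export
mesh_stats <- function(mesh) {
  ne <- nrow(mesh_edges(mesh))
  watertight <- FALSE
  if (nrow(mesh$triangles) > 0) {
    cnt <- edge_use_counts(mesh)$count
    watertight <- all(cnt == 2L)
  }
  mean_edge <- if (ne > 0) {
    e <- mesh_edges(mesh)
    mean(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2)))
  } else NA_real_
  list(vertices = nrow(mesh$vertices), triangles = nrow(mesh$triangles),
       mean_edge = mean_edge, watertight = watertight,
       euler = nrow(mesh$vertices) - ne + nrow(mesh$triangles))
}

#' Exact point-to-mesh distance
#'
#' Euclidean distance from each query point to the closest point on any
#' triangle of the mesh (vertex, edge and face cases all handled), using a
#' bounding-volume tree; results are identical to an exhaustive per-triangle
#' scan.
#'
#' @param p a length-3 point or an n x 3 matrix of points.
#' @param mesh a non-empty [tri_mesh()].
#' @return For a single point, a list with `distance`, `point` (closest point
#'   on the mesh) and `tri` (triangle index). For a matrix, a list with
#'   vector `distance`, matrix `point` and vector `tri`.
#' @export
point_mesh_distance <- function(p, mesh) {
  if (nrow(mesh$triangles) == 0) stop("empty mesh")
  single <- is.null(dim(p))
  P <- if (single) matrix(p, ncol = 3) else as.matrix(p)
  res <- cpp_closest_on_mesh(mesh$vertices, mesh$triangles, P)
  if (single)
    list(distance = res$dist[1], point = drop(res$point[1, ]), tri = res$tri[1])
  else
    list(distance = res$dist, point = res$point, tri = res$tri)
}

#' Keep a subset of vertices
#'
#' Drops all other vertices, every triangle touching a dropped vertex, and
#' reindexes; normals and labels follow the kept vertices. Never adds
#' vertices.
#'
#' @param mesh a [tri_mesh()].
#' @param keep logical vector (one per vertex) or integer indices.
#' @return A [tri_mesh()].
#' @export
mesh_subset_vertices <- function(mesh, keep) {
  nv <- nrow(mesh$vertices)
  if (is.logical(keep)) keep <- which(keep)
  map <- integer(nv)
  map[keep] <- seq_along(keep)
  tri <- mesh$triangles
  ok <- rowSums(matrix(tri %in% keep, ncol = 3)) == 3L
  tri <- matrix(map[tri[ok, , drop = FALSE]], ncol = 3)
  tri_mesh(mesh$vertices[keep, , drop = FALSE], tri,
           normals = if (!is.null(mesh$normals)) mesh$normals[keep, , drop = FALSE],
           labels = if (!is.null(mesh$labels)) mesh$labels[keep],
           validate = FALSE)
}

#' Connected components of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return Integer vector assigning a component id to every vertex (isolated
#'   vertices form their own components).
#' @export
mesh_components <- function(mesh) {
  g <- igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Keep the largest connected component
#'
#' Component size is measured in vertices; ties break toward the lowest
#' component id.
#'
#' @param mesh a [tri_mesh()].
#' @return A [tri_mesh()].
#' @export
largest_component <- function(mesh) {
  keep_components(mesh, min_frac = 1)
}

#' Drop small connected components
#'
#' Keeps every component whose vertex count is at least `min_frac` times the
#' largest component's. Fence occlusion legitimately slices a single surface
#' into several large strips, so keeping only the single largest component
#' would discard real surface; small isolated blobs (noise) still go.
#'
#' @param mesh a [tri_mesh()].
#' @param min_frac fraction of the largest component below which a component
#'   is dropped (1 keeps only the largest).
#' @return A [tri_mesh()].
#' @export
keep_components <- function(mesh, min_frac = 0.1) {
  if (nrow(mesh$vertices) == 0) return(mesh)
  comp <- mesh_components(mesh)
  sizes <- tabulate(comp)
  keep_ids <- which(sizes >= min_frac * max(sizes))
  mesh_subset_vertices(mesh, comp %in% keep_ids)
}
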