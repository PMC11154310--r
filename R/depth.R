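# Depth-image ingestion: pinhole back-projection of a depth grid to an
# organized point cloud, and triangulation of the pixel grid into a mesh.
# Pixel coordinates are 0-based: pixel (u, v) is column u+1, row v+1 of the
# depth matrix, and the principal point defaults to the image center.

#' Camera intrinsics
#'
#' Pinhole intrinsics: focal lengths and principal point in pixels. The
#' defaults model the depth camera used on the capture rig (69.4 x 42.5
#' degree field of view at 1280 x 720).
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels; default image center.
#' @param width,height image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx = 925, fy = 925, width = 1280L, height = 720L,
                              cx = (width - 1) / 2, cy = (height - 1) / 2) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Rescale intrinsics to a different image resolution
#'
#' Focal lengths and principal point scale per axis so the field of view is
#' preserved.
#'
#' @param K a [camera_intrinsics()].
#' @param width,height target resolution.
#' @return A [camera_intrinsics()].
#' @export
scale_intrinsics <- function(K, width, height) {
  sx <- width / K$width
  sy <- height / K$height
  camera_intrinsics(fx = K$fx * sx, fy = K$fy * sy,
                    width = width, height = height,
                    cx = (K$cx + 0.5) * sx - 0.5, cy = (K$cy + 0.5) * sy - 0.5)
}

#' Depth image
#'
#' A grid of depth values in meters on the pixel grid with a validity mask:
#' a pixel is valid when its depth is finite and inside the working range
#' (0.1 m to 20 m); zero encodes "no measurement".
#'
#' @param depth height x width numeric matrix of depths in meters.
#' @return An object of class `depth_image` with elements `depth` and
#'   `valid`.
#' @export
depth_image <- function(depth) {
  depth <- as.matrix(depth)
  valid <- is.finite(depth) & depth > 0.1 & depth < 20
  structure(list(depth = depth, valid = valid,
                 height = nrow(depth), width = ncol(depth)),
            class = "depth_image")
}

#' Back-project a depth image to an organized point cloud
#'
#' Pinhole model: a pixel (u, v) with depth z maps to the camera-frame point
#' (x, y, z) with x = (u - cx) z / fx and y = (v - cy) z / fy. Invalid pixels
#' are masked and emit no point. The grid layout is retained so the cloud can
#' be triangulated.
#'
#' @param depth a [depth_image()] or depth matrix in meters.
#' @param K a [camera_intrinsics()] whose size matches the depth grid.
#' @param labels optional per-pixel label matrix, carried to the points.
#' @return An object of class `organized_cloud`: `points` ((h*w) x 3, NA on
#'   invalid pixels, row-major in v then u), `valid` mask, `labels`, `K`.
#' @export
backproject <- function(depth, K, labels = NULL) {
  if (!inherits(depth, "depth_image")) depth <- depth_image(depth)
  if (depth$height != K$height || depth$width != K$width)
    stop("depth image is ", depth$height, "x", depth$width,
         " but intrinsics expect ", K$height, "x", K$width)
  if (!is.null(labels) && !all(dim(labels) == c(depth$height, depth$width)))
    stop("label matrix must match the depth grid")
  u <- matrix(0:(K$width - 1), depth$height, depth$width, byrow = TRUE)
  v <- matrix(0:(K$height - 1), depth$height, depth$width)
  z <- depth$depth
  z[!depth$valid] <- NA_real_
  pts <- cbind(x = as.vector((u - K$cx) * z / K$fx),
               y = as.vector((v - K$cy) * z / K$fy),
               z = as.vector(z))
  structure(list(points = pts, valid = depth$valid,
                 labels = if (!is.null(labels)) as.vector(labels),
                 K = K, height = depth$height, width = depth$width),
            class = "organized_cloud")
}

#' @export
print.organized_cloud <- function(x, ...) {
  cat(sprintf("<organized_cloud> %dx%d grid, %d valid points\n",
              x$height, x$width, sum(x$valid)))
  invisible(x)
}

#' Project camera-frame points to pixel coordinates
#'
#' @param pts n x 3 matrix of camera-frame points.
#' @param K a [camera_intrinsics()].
#' @return n x 2 matrix of (u, v) pixel coordinates (0-based).
#' @export
project_points <- function(pts, K) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cbind(u = K$fx * pts[, 1] / pts[, 3] + K$cx,
        v = K$fy * pts[, 2] / pts[, 3] + K$cy)
}

#' Triangulate an organized point cloud over the pixel grid
#'
#' Every 2x2 pixel cell whose four corners are all valid yields two
#' counter-clockwise triangles (as seen from the camera), split along the
#' fixed diagonal (v,u)-(v+1,u)-(v,u+1) / (v+1,u)-(v+1,u+1)-(v,u+1).
#' Triangles whose three back-projected points are collinear (area below
#' 1e-12 m^2) are skipped. Each vertex normal is the normalized average of
#' the unit normals of its incident triangles, oriented toward the camera.
#'
#' @param cloud an [organized_cloud()].
#' @return A [tri_mesh()] whose vertices are the valid points (grid order),
#'   with normals and any labels attached.
#' @export
triangulate_grid <- function(cloud) {
  h <- cloud$height
  w <- cloud$width
  valid <- cloud$valid
  idx <- matrix(0L, h, w)
  idx[valid] <- seq_len(sum(valid))
  V <- cloud$points[as.vector(valid), , drop = FALSE]
  if (h < 2 || w < 2 || sum(valid) == 0)
    return(tri_mesh(V, matrix(integer(), ncol = 3),
                    labels = cloud$labels[as.vector(valid)], validate = FALSE))
  cell_ok <- valid[-h, -w] & valid[-1, -w] & valid[-h, -1] & valid[-1, -1]
  A <- idx[-h, -w][cell_ok]   # (v, u)
  B <- idx[-1, -w][cell_ok]   # (v+1, u)
  C <- idx[-h, -1][cell_ok]   # (v, u+1)
  D <- idx[-1, -1][cell_ok]   # (v+1, u+1)
  tri <- rbind(cbind(A, B, C), cbind(B, D, C))
  # drop degenerate (collinear in 3D) triangles
  a <- V[tri[, 1], , drop = FALSE]
  u1 <- V[tri[, 2], , drop = FALSE] - a
  u2 <- V[tri[, 3], , drop = FALSE] - a
  cr <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
              u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
              u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  tri <- tri[area >= 1e-12, , drop = FALSE]
  mesh <- tri_mesh(V, tri, labels = cloud$labels[as.vector(valid)],
                   validate = FALSE)
  mesh$normals <- vertex_normals(mesh)
  mesh
}
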