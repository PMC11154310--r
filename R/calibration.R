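# Sphere-target extrinsic calibration. A rig of spheres with mutually
# distinct pairwise center distances is observed by every camera; distances
# identify corresponding centers across cameras, and the rigid transform
# between two cameras follows in closed form from the matched centers.

#' Fit a sphere to 3D points
#'
#' Algebraic least-squares fit (the linearization |p|^2 = 2 c.p + (r^2 -
#' |c|^2)) followed by geometric Gauss-Newton refinement of the radial
#' residuals |p - c| - r. Exact on noiseless data, including partial
#' (hemisphere) coverage.
#'
#' @param points n x 3 matrix, n >= 4, not coplanar.
#' @return An object of class `sphere_observation` with `center` (meters),
#'   `radius` (meters), `inliers` (point count) and `rms` residual.
#' @export
fit_sphere <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4) stop("points are coplanar: sphere fit is degenerate")
  beta <- qr.coef(qr_A, b)
  center <- beta[1:3]
  radius <- sqrt(max(beta[4] + sum(center^2), 0))
  # geometric refinement
  for (i in 1:20) {
    d <- sweep(points, 2, center)
    len <- sqrt(rowSums(d^2))
    r_res <- len - radius
    J <- cbind(-d / len, -1)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r_res)),
                     error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- radius + step[4]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  d <- sweep(points, 2, center)
  rms <- sqrt(mean((sqrt(rowSums(d^2)) - radius)^2))
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 inliers = nrow(points), rms = rms),
            class = "sphere_observation")
}

#' @export
print.sphere_observation <- function(x, ...) {
  cat(sprintf("<sphere_observation> center (%.4f, %.4f, %.4f) m, radius %.4f m, %d points\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$inliers))
  invisible(x)
}

#' Closed-form rigid transform from point correspondences
#'
#' Kabsch scheme: centroid alignment plus the rotation from the SVD of the
#' cross-covariance, with the reflection guard. Returns the transform T such
#' that dst ~= R src + t.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3).
#' @return A [rigid_transform()] mapping src coordinates into dst.
#' @export
kabsch_transform <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 3)
  dst <- matrix(as.numeric(dst), ncol = 3)
  if (nrow(src) != nrow(dst) || nrow(src) < 3)
    stop("need at least 3 corresponding points")
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  s <- svd(H)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- cd - R %*% cs
  m[1:3, 1:3] <- project_rotation(m[1:3, 1:3])
  rigid_transform(m)
}

#' Register a sphere rig between two cameras
#'
#' The calibration rig is built so every pairwise distance between sphere
#' centers is distinct; matching the sorted distance signature of each
#' center therefore identifies correspondences without labels. The rigid
#' transform then follows from [kabsch_transform()].
#'
#' @param centers_a,centers_b n x 3 matrices of sphere centers seen by
#'   cameras a and b (n >= 3; the same spheres, any order).
#' @param tol distance-matching tolerance in meters (default 5 mm). If any
#'   two pairwise distances within a camera agree within `tol` the
#'   correspondence is ambiguous and an error is raised.
#' @return A [rigid_transform()] mapping camera-b coordinates into camera a.
#' @export
register_sphere_rig <- function(centers_a, centers_b, tol = 0.005) {
  A <- matrix(as.numeric(centers_a), ncol = 3)
  B <- matrix(as.numeric(centers_b), ncol = 3)
  if (nrow(A) < 3 || nrow(B) < 3) stop("need at least 3 spheres in both cameras")
  da <- as.matrix(stats::dist(A))
  db <- as.matrix(stats::dist(B))
  check_distinct <- function(dm, who) {
    v <- sort(dm[upper.tri(dm)])
    if (length(v) > 1 && any(diff(v) < tol))
      stop("ambiguous sphere rig in camera ", who,
           ": two pairwise distances agree within ", tol, " m")
  }
  check_distinct(da, "a")
  check_distinct(db, "b")
  # signature of a center: its sorted distances to all other centers; match
  # each center to the candidate with the smallest mean discrepancy (robust
  # to measurement noise on individual distances; ambiguity is excluded by
  # the distinctness check above)
  sig_a <- apply(da, 1, function(r) sort(r[r > 0]))
  sig_b <- apply(db, 1, function(r) sort(r[r > 0]))
  match_b <- integer(nrow(A))
  for (i in seq_len(nrow(A))) {
    score <- vapply(seq_len(nrow(B)), function(j) {
      if (length(sig_b[, j]) != length(sig_a[, i])) return(Inf)
      mean(abs(sig_b[, j] - sig_a[, i]))
    }, numeric(1))
    match_b[i] <- if (min(score) < tol) which.min(score) else NA_integer_
  }
  if (anyDuplicated(match_b[!is.na(match_b)]))
    stop("ambiguous sphere correspondence: two centers match the same candidate")
  ok <- !is.na(match_b)
  if (sum(ok) < 3)
    stop("fewer than 3 sphere correspondences found (", sum(ok), ")")
  kabsch_transform(B[match_b[ok], , drop = FALSE], A[ok, , drop = FALSE])
}

#' Chain pairwise sphere calibrations to a reference camera
#'
#' Registers each camera's sphere centers to camera 1's (the world frame),
#' producing the initial extrinsic pose for every camera.
#'
#' @param centers_list list of n x 3 center matrices, one per camera.
#' @param tol distance-matching tolerance in meters.
#' @return List of [rigid_transform()] poses (camera-to-world); the first is
#'   the identity.
#' @export
calibrate_rig <- function(centers_list, tol = 0.005) {
  stopifnot(length(centers_list) >= 2)
  lapply(seq_along(centers_list), function(i) {
    if (i == 1) rigid_transform()
    else register_sphere_rig(centers_list[[1]], centers_list[[i]], tol)
  })
}
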