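# Rigid-transform algebra and the small-angle pose parameterization used by
# the camera-pose optimizer. Internal units are meters and radians throughout;
# millimeters appear only at I/O and reporting boundaries.

#' Rigid transform
#'
#' A 4x4 homogeneous transform whose rotation block is orthonormal with
#' determinant +1 (checked to 1e-9) and whose last row is (0,0,0,1). Used for
#' camera poses: the transform maps camera-frame coordinates into the world
#' frame, with translations in meters.
#'
#' @param matrix 4x4 numeric matrix.
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform()                 # identity
#' rigid_transform(diag(4))
#' @export
rigid_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || !all(dim(matrix) == c(4, 4)) || !all(is.finite(matrix)))
    stop("a rigid transform is a finite 4x4 numeric matrix")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 0)
    stop("last row of a rigid transform must be exactly (0,0,0,1)")
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || det(R) < 0)
    stop("rotation block must be orthonormal with determinant +1 (tolerance 1e-9)")
  structure(list(matrix = matrix), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  translation (m):",
      paste(sprintf("%.4f", x$matrix[1:3, 4]), collapse = " "), "\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x object to coerce or test.
#' @export
as_rigid_transform <- function(x) {
  if (inherits(x, "rigid_transform")) return(x)
  rigid_transform(x)
}

#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @describeIn rigid_transform rotation block (3x3).
#' @param T a `rigid_transform`.
#' @export
rotation <- function(T) as_rigid_transform(T)$matrix[1:3, 1:3]

#' @describeIn rigid_transform translation (length-3, meters).
#' @export
translation <- function(T) as_rigid_transform(T)$matrix[1:3, 4]

#' Compose and invert rigid transforms
#'
#' @param a,b `rigid_transform` objects (or 4x4 matrices).
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(as_rigid_transform(a)$matrix %*% as_rigid_transform(b)$matrix)
}

#' @rdname compose_transforms
#' @param T a `rigid_transform`.
#' @export
invert_transform <- function(T) {
  m <- as_rigid_transform(T)$matrix
  R <- t(m[1:3, 1:3])
  out <- diag(4)
  out[1:3, 1:3] <- R
  out[1:3, 4] <- -R %*% m[1:3, 4]
  rigid_transform(out)
}

#' Exact rotation about an axis (Rodrigues formula)
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Project a near-rotation matrix to the nearest rotation
#'
#' Polar projection via SVD; used after every linearized pose update so that
#' orthonormality drift cannot accumulate over iterations.
#'
#' @param R 3x3 matrix close to a rotation.
#' @return The nearest 3x3 rotation matrix (Frobenius sense).
#' @export
project_rotation <- function(R) {
  s <- svd(R)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

#' Pose increment (small-angle parameterization)
#'
#' The 6-vector xi = (alpha, beta, gamma, t0, t1, t2) parameterizing an
#' incremental transform: alpha, beta, gamma are small rotations (radians)
#' about the x, y and z axes respectively, and (t0, t1, t2) is a translation
#' in meters. The linearized update matrix is
#' \deqn{L(\xi) = \begin{pmatrix} 1 & -\gamma & \beta & t_0 \\ \gamma & 1 &
#' -\alpha & t_1 \\ -\beta & \alpha & 1 & t_2 \\ 0 & 0 & 0 & 1 \end{pmatrix}}
#' i.e. identity plus the skew matrix of (alpha, beta, gamma). The
#' linearization is intended for angles below about 0.06 rad (~3 degrees).
#'
#' @param alpha,beta,gamma rotations about x, y, z in radians.
#' @param t0,t1,t2 translation components in meters.
#' @return An object of class `pose_increment` (named numeric of length 6).
#' @export
pose_increment <- function(alpha = 0, beta = 0, gamma = 0, t0 = 0, t1 = 0, t2 = 0) {
  xi <- c(alpha = alpha, beta = beta, gamma = gamma, t0 = t0, t1 = t1, t2 = t2)
  if (!all(is.finite(xi))) stop("pose increment must be finite")
  structure(xi, class = "pose_increment")
}

#' @rdname pose_increment
#' @param xi a `pose_increment` or numeric vector of length 6.
#' @export
as_pose_increment <- function(xi) {
  if (inherits(xi, "pose_increment")) return(xi)
  xi <- as.numeric(xi)
  if (length(xi) != 6) stop("a pose increment has 6 components")
  pose_increment(xi[1], xi[2], xi[3], xi[4], xi[5], xi[6])
}

#' @describeIn pose_increment the linearized 4x4 update matrix L(xi).
#' @export
increment_matrix <- function(xi) {
  xi <- as_pose_increment(xi)
  matrix(c(1, xi[3], -xi[2], 0,
           -xi[3], 1, xi[1], 0,
           xi[2], -xi[1], 1, 0,
           xi[4], xi[5], xi[6], 1), 4, 4)
}

#' Apply a linearized pose increment to a transform
#'
#' Computes L(xi) * T and re-orthonormalizes the rotation block (nearest
#' rotation), so the result is a valid rigid transform even though L(xi)
#' itself is only approximately orthogonal.
#'
#' @param xi a [pose_increment()] (or length-6 numeric).
#' @param T a [rigid_transform()].
#' @return A `rigid_transform`.
#' @examples
#' T <- rigid_transform()
#' apply_increment(pose_increment(t0 = 0.01), T)$matrix[1, 4]  # 0.01 m in x
#' @export
apply_increment <- function(xi, T) {
  xi <- as_pose_increment(xi)
  T <- as_rigid_transform(T)
  m <- increment_matrix(xi) %*% T$matrix
  m[1:3, 1:3] <- project_rotation(m[1:3, 1:3])
  m[4, ] <- c(0, 0, 0, 1)
  rigid_transform(m)
}

#' Extract the small-angle parameters of a near-identity transform
#'
#' Inverse of the linearized parameterization: the translation is read
#' directly and the rotation parameters are recovered from the antisymmetric
#' part of the rotation block, rescaled so that [apply_increment()] (whose
#' update is projected to the nearest rotation) reproduces the input
#' exactly; for small angles the parameters agree with the rotation angles
#' to third order.
#'
#' @param T_rel a `rigid_transform` whose rotation is close to identity
#'   (rotation trace must exceed 2.8, about 18 degrees, else the
#'   linearization is invalid and an error is raised).
#' @return A [pose_increment()].
#' @export
extract_increment <- function(T_rel) {
  T_rel <- as_rigid_transform(T_rel)
  R <- T_rel$matrix[1:3, 1:3]
  tr <- sum(diag(R))
  if (tr < 2.8)
    stop("rotation too far from identity (trace ", signif(tr, 4),
         " < 2.8): small-angle linearization invalid")
  A <- (R - t(R)) / 2
  w <- c(A[3, 2], A[1, 3], A[2, 1])
  s <- sqrt(sum(w^2))             # sin(theta)
  if (s > 1e-12) {
    theta <- asin(min(1, s))
    # scaled so that the nearest-rotation projection of I + skew(w) is
    # exactly the rotation by theta: apply/extract round-trip exactly
    w <- w * tan(theta) / s
  }
  pose_increment(w[1], w[2], w[3],
                 T_rel$matrix[1, 4], T_rel$matrix[2, 4], T_rel$matrix[3, 4])
}

#' Regularizer weights
#'
#' Dimensionless weights on the squared rotation parameters (kr) and squared
#' translation parameters (kt, applied to meters squared) of the pose anchor
#' term. Defaults keep one degree of rotation or one centimeter of
#' translation comparable to a single millimeter-scale data residual.
#'
#' @param kr weight on squared rotation parameters (>= 0).
#' @param kt weight on squared translation parameters (>= 0).
#' @return An object of class `regularizer_weights`.
#' @export
regularizer_weights <- function(kr = 1e2, kt = 1e4) {
  if (!is.finite(kr) || !is.finite(kt) || kr < 0 || kt < 0)
    stop("kr and kt must be finite and non-negative")
  structure(list(kr = kr, kt = kt), class = "regularizer_weights")
}

#' Pose anchor regularizer
#'
#' The distance of a camera pose from its calibrated initial pose:
#' \deqn{\Gamma(T_i, T_i^0) = k_r (r_0^2 + r_1^2 + r_2^2) +
#'   k_t (t_0^2 + t_1^2 + t_2^2)}
#' where the parameters are extracted from the relative transform
#' `inv(Ti0) * Ti` in the initial camera's frame. It is zero iff the two
#' poses coincide, and keeps optimized cameras from drifting away from their
#' calibration while still letting the data term align them.
#'
#' @param Ti current camera pose.
#' @param Ti0 initial (calibrated) camera pose.
#' @param w a [regularizer_weights()].
#' @return Non-negative scalar.
#' @export
gamma_regularizer <- function(Ti, Ti0, w = regularizer_weights()) {
  rel <- compose_transforms(invert_transform(Ti0), Ti)
  xi <- extract_increment(rel)
  w$kr * sum(xi[1:3]^2) + w$kt * sum(xi[4:6]^2)
}

# Internal: the six weighted anchor residuals (sqrt-weighted so that their
# sum of squares equals gamma_regularizer); used by the Gauss-Newton solver.
gamma_residuals <- function(Ti, Ti0, w) {
  rel <- compose_transforms(invert_transform(Ti0), Ti)
  xi <- extract_increment(rel)
  c(sqrt(w$kr) * xi[1:3], sqrt(w$kt) * xi[4:6])
}

#' Rotation angle between two rotations, degrees
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Angle of `Ra %*% t(Rb)` in degrees.
#' @export
rotation_angle_deg <- function(Ra, Rb = diag(3)) {
  R <- Ra %*% t(Rb)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
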