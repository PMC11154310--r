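# Independent reference implementations used as oracles. They share no code
# with the package internals: plain-R exhaustive scans and closed forms.

# Closest point on one triangle, by brute projection onto the plane and the
# three edges/vertices.
oracle_closest_on_triangle <- function(p, a, b, c) {
  cands <- list(a, b, c)
  seg <- function(u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    u + min(max(t, 0), 1) * (v - u)
  }
  cands <- c(cands, list(seg(a, b), seg(b, c), seg(c, a)))
  n <- pracma::cross(b - a, c - a)
  if (sum(n^2) > 0) {
    n <- n / sqrt(sum(n^2))
    foot <- p - sum((p - a) * n) * n
    # barycentric check
    v0 <- b - a; v1 <- c - a; v2 <- foot - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) cands <- c(cands, list(foot))
  }
  d <- vapply(cands, function(x) sqrt(sum((p - x)^2)), numeric(1))
  cands[[which.min(d)]]
}

# Exhaustive point-to-mesh distance.
oracle_point_mesh_distance <- function(p, mesh) {
  best <- Inf
  for (t in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[t, ]
    cp <- oracle_closest_on_triangle(p, mesh$vertices[tri[1], ],
                                     mesh$vertices[tri[2], ],
                                     mesh$vertices[tri[3], ])
    best <- min(best, sqrt(sum((p - cp)^2)))
  }
  best
}

# Brute-force nearest-neighbour distances.
oracle_nn_dist <- function(ref, query) {
  apply(query, 1, function(q) sqrt(min(colSums((t(ref) - q)^2))))
}

# Independent point-to-plane ICP against a fixed mesh: exhaustive closest
# points, analytic 6x6 linear solve, small-angle update with SVD
# re-orthonormalization, truncated objective identical in form to the
# package's (excluded correspondences cost the cutoff).
oracle_icp <- function(points, T0, mesh, cutoff = 0.14, iters = 30) {
  fn <- matrix(0, nrow(mesh$triangles), 3)
  for (t in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[t, ]
    n <- pracma::cross(mesh$vertices[tri[2], ] - mesh$vertices[tri[1], ],
                       mesh$vertices[tri[3], ] - mesh$vertices[tri[1], ])
    fn[t, ] <- n / sqrt(sum(n^2))
  }
  closest <- function(p) {
    best <- Inf; bt <- 1; bc <- NULL
    for (t in seq_len(nrow(mesh$triangles))) {
      tri <- mesh$triangles[t, ]
      cp <- oracle_closest_on_triangle(p, mesh$vertices[tri[1], ],
                                       mesh$vertices[tri[2], ],
                                       mesh$vertices[tri[3], ])
      d <- sqrt(sum((p - cp)^2))
      if (d < best) { best <- d; bt <- t; bc <- cp }
    }
    list(d = best, tri = bt, cp = bc)
  }
  Tm <- T0
  objective <- NA_real_
  for (it in seq_len(iters)) {
    q <- sweep(points %*% t(Tm[1:3, 1:3]), 2, Tm[1:3, 4], "+")
    rows <- lapply(seq_len(nrow(q)), function(i) closest(q[i, ]))
    d <- vapply(rows, `[[`, numeric(1), "d")
    valid <- d <= cutoff
    r <- vapply(seq_along(rows), function(i)
      sum(fn[rows[[i]]$tri, ] * (q[i, ] - rows[[i]]$cp)), numeric(1))
    robj <- abs(r); robj[!valid] <- cutoff
    objective <- sum((1000 * robj)^2)
    J <- t(vapply(seq_along(rows), function(i) {
      n <- fn[rows[[i]]$tri, ]
      1000 * c(pracma::cross(q[i, ], n), n)
    }, numeric(6)))
    Jv <- J[valid, , drop = FALSE]
    rv <- 1000 * r[valid]
    delta <- solve(crossprod(Jv), -crossprod(Jv, rv))
    L <- diag(4)
    L[1, 2] <- -delta[3]; L[2, 1] <- delta[3]
    L[1, 3] <- delta[2]; L[3, 1] <- -delta[2]
    L[2, 3] <- -delta[1]; L[3, 2] <- delta[1]
    L[1:3, 4] <- delta[4:6]
    Tm <- L %*% Tm
    s <- svd(Tm[1:3, 1:3])
    Tm[1:3, 1:3] <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    Tm[4, ] <- c(0, 0, 0, 1)
    if (sqrt(sum(delta^2)) < 1e-12) break
  }
  list(T = Tm, objective = objective)
}

# Quasi-uniform sphere sampling (Fibonacci spiral).
fib_sphere <- function(n, r = 0.5) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  v <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  list(points = r * v, normals = v)
}

# Small toy rig: three cameras on a ring observing overlapping patches of a
# sphere surface, clouds stored in each camera's own frame; optional uniform
# pose perturbation applied to the initial poses.
toy_rig <- function(n_per = 300, seed = 1, perturb = NULL, radius = 0.5) {
  set.seed(seed)
  sph <- fib_sphere(3 * n_per, r = radius)
  look_at <- function(center) {
    z <- -center / sqrt(sum(center^2))
    x <- c(-z[2], z[1], 0)
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    m <- diag(4)
    m[1:3, 1] <- x; m[1:3, 2] <- y; m[1:3, 3] <- z; m[1:3, 4] <- center
    m[1:3, 1:3] <- project_rotation(m[1:3, 1:3])
    rigid_transform(m)
  }
  cams <- lapply(0:2, function(s) {
    ang <- atan2(sph$points[, 2], sph$points[, 1])
    ctr <- -pi + (2 * pi / 3) * (s + 0.5)
    dd <- abs(atan2(sin(ang - ctr), cos(ang - ctr)))
    keep <- dd < (2 * pi / 3)
    center <- 2 * c(cos(ctr), sin(ctr), 0.3)
    pose_true <- look_at(center)
    pose_init <- pose_true
    if (!is.null(perturb)) {
      ang3 <- runif(3, -perturb[1], perturb[1])
      tr3 <- runif(3, -perturb[2], perturb[2])
      P <- diag(4)
      P[1:3, 1:3] <- rotation_about_axis(c(1, 0, 0), ang3[1]) %*%
        rotation_about_axis(c(0, 1, 0), ang3[2]) %*%
        rotation_about_axis(c(0, 0, 1), ang3[3])
      P[1:3, 4] <- tr3
      pose_init <- compose_transforms(pose_true, rigid_transform(P))
    }
    inv <- invert_transform(pose_true)
    list(id = s, pose_init = pose_init, pose_true = pose_true,
         points = transform_points(sph$points[keep, , drop = FALSE], inv),
         normals = transform_points(sph$normals[keep, , drop = FALSE], inv,
                                    vectors = TRUE))
  })
  camera_rig(cams)
}

# A flat grid mesh of r x c vertices in a plane (unit spacing).
grid_patch <- function(r, c) {
  depth <- matrix(2, r, c)
  K <- camera_intrinsics(fx = 1, fy = 1, width = c, height = r,
                        cx = (c - 1) / 2, cy = (r - 1) / 2)
  triangulate_grid(backproject(depth, K))
}
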