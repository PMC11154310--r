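# Multi-camera pose refinement. The global objective is
#   E(T) = sum_i sum_{p in P_i} Dist(M, T_i p)^2 + sum_i Gamma(T_i, T_i0)
# where M is the surface reconstructed from all cameras, P_i the overlap
# subset of camera i, Dist the point-to-plane distance to the closest mesh
# point (in millimeters inside the objective), and Gamma the anchor to the
# calibrated pose. The interleaved optimizer alternates rebuilding M with
# per-camera Gauss-Newton minimization of the six pose parameters.

#' Registration configuration
#'
#' @param kr,kt anchor regularizer weights (on squared radians and squared
#'   meters respectively, against a data term in squared millimeters). The
#'   defaults put the anchor at roughly a percent of the typical data-term
#'   stiffness of a few thousand points: strong enough to suppress drift of
#'   the weakly-constrained tangential pose directions -- the stated purpose
#'   of the anchor -- while conceding to any feature-supported alignment
#'   signal.
#' @param overlap_threshold overlap-set distance threshold in meters. The
#'   default 0.1 m matches the calibration error bound the optimizer is
#'   designed to absorb.
#' @param cutoff valid-correspondence cutoff in meters: correspondences
#'   farther than this from the mesh are excluded from the objective
#'   (default 0.14 m).
#' @param max_iter maximum interleaved iterations (default 25).
#' @param conv_tol_mm stop when the mean residual changes by no more than
#'   this between successive iterations (default 0.05 mm).
#' @param depth_intermediate,depth_final reconstruction depth for the
#'   per-iteration mesh (8, smooth) and the final mesh (9, more detail).
#' @param max_inner,step_tol inner Gauss-Newton iteration cap and step-norm
#'   stopping tolerance per camera alignment.
#' @param lm_damping Levenberg damping of the Gauss-Newton system, as a
#'   fraction of the mean diagonal; stabilizes the weakly-constrained
#'   tangential directions.
#' @param max_align_points per-camera cap on the points used by the
#'   Gauss-Newton aligner (a deterministic subsample; the alignment is
#'   bias-limited, not variance-limited, so a few thousand points suffice).
#' @param trim_quantile,band passed to [reconstruct_surface()] for the final
#'   mesh (intermediate meshes skip the fringe trim; the narrow band already
#'   bounds them).
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(kr = 1e7, kt = 1e7, overlap_threshold = 0.10,
                                cutoff = 0.14, max_iter = 25, conv_tol_mm = 0.05,
                                depth_intermediate = 8, depth_final = 9,
                                max_inner = 10, step_tol = 1e-8,
                                lm_damping = 1e-3, max_align_points = 2500,
                                trim_quantile = 0.01, band = NULL) {
  stopifnot(kr >= 0, kt >= 0, overlap_threshold > 0, cutoff > 0,
            max_iter >= 1, conv_tol_mm > 0, max_inner >= 1)
  structure(list(kr = kr, kt = kt, overlap_threshold = overlap_threshold,
                 cutoff = cutoff, max_iter = max_iter, conv_tol_mm = conv_tol_mm,
                 depth_intermediate = depth_intermediate,
                 depth_final = depth_final, max_inner = max_inner,
                 step_tol = step_tol, lm_damping = lm_damping,
                 max_align_points = max_align_points,
                 trim_quantile = trim_quantile, band = band),
            class = "registration_config")
}

#' Transform points or direction vectors by a rigid transform
#'
#' @param points n x 3 matrix.
#' @param T a [rigid_transform()].
#' @param vectors if TRUE, apply the rotation only (for normals).
#' @return n x 3 matrix.
#' @export
transform_points <- function(points, T, vectors = FALSE) {
  T <- as_rigid_transform(T)
  out <- matrix(as.numeric(points), ncol = 3) %*% t(T$matrix[1:3, 1:3])
  if (!vectors) out <- sweep(out, 2, T$matrix[1:3, 4], "+")
  out
}

#' Camera rig
#'
#' The registration input: per camera an id, intrinsics, the calibrated
#' initial pose, the current pose (starts at the initial), optionally the
#' ground-truth pose (simulator), and the segmented cloud (points + unit
#' normals in the camera frame).
#'
#' @param cameras list of camera entries; each needs `pose_init`
#'   (camera-to-world [rigid_transform()]), `points`, `normals`, and may
#'   carry `id`, `K`, `pose_true`, `labels`.
#' @return An object of class `camera_rig`.
#' @export
camera_rig <- function(cameras) {
  if (length(cameras) < 2) stop("a rig needs at least 2 cameras")
  cams <- lapply(seq_along(cameras), function(i) {
    cam <- cameras[[i]]
    if (is.null(cam$pose_init)) stop("camera ", i, " lacks pose_init")
    cam$pose_init <- as_rigid_transform(cam$pose_init)
    if (!is.null(cam$pose_true)) cam$pose_true <- as_rigid_transform(cam$pose_true)
    if (is.null(cam$pose)) cam$pose <- cam$pose_init
    if (is.null(cam$id)) cam$id <- i - 1L
    cam$points <- matrix(as.numeric(cam$points), ncol = 3)
    cam$normals <- matrix(as.numeric(cam$normals), ncol = 3)
    if (nrow(cam$points) != nrow(cam$normals))
      stop("camera ", cam$id, ": points/normals mismatch")
    cam
  })
  structure(list(cameras = cams), class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  n <- vapply(x$cameras, function(c) nrow(c$points), integer(1))
  cat(sprintf("<camera_rig> %d cameras, %s points per camera\n",
              length(x$cameras), paste(n, collapse = "/")))
  invisible(x)
}

#' Rig poses
#'
#' @param rig a [camera_rig()].
#' @param which one of "current", "init", "true".
#' @return List of [rigid_transform()].
#' @export
rig_poses <- function(rig, which = c("current", "init", "true")) {
  which <- match.arg(which)
  field <- switch(which, current = "pose", init = "pose_init", true = "pose_true")
  lapply(rig$cameras, function(cam) cam[[field]])
}

#' Set rig poses
#'
#' @param rig a [camera_rig()].
#' @param poses list of [rigid_transform()], one per camera.
#' @return The updated rig.
#' @export
set_rig_poses <- function(rig, poses) {
  stopifnot(length(poses) == length(rig$cameras))
  for (i in seq_along(poses)) rig$cameras[[i]]$pose <- as_rigid_transform(poses[[i]])
  rig
}

#' Overlap sets
#'
#' For each camera i, the indices of its points whose world-frame distance
#' (at the current poses, normally the initial ones) to the nearest point of
#' any other camera's cloud is at most `threshold`. These subsets carry the
#' data term; they are computed once before the interleaved loop and not
#' refreshed.
#'
#' @param rig a [camera_rig()].
#' @param threshold overlap distance in meters.
#' @return List of integer index vectors, one per camera. A camera with an
#'   empty overlap set triggers a warning (it then contributes only through
#'   the regularizer).
#' @export
compute_overlap <- function(rig, threshold = 0.10) {
  world <- lapply(rig$cameras, function(cam) transform_points(cam$points, cam$pose))
  lapply(seq_along(world), function(i) {
    ref <- do.call(rbind, world[-i])
    d <- cpp_knn(ref, world[[i]], 1)$dist[, 1]
    idx <- which(d <= threshold)
    if (length(idx) == 0)
      warning("camera ", rig$cameras[[i]]$id,
              " has an empty overlap set; it is constrained only by the regularizer")
    idx
  })
}

# Internal: reusable closest-point structure (BVH) plus face normals for one
# mesh; amortizes tree construction over the many queries of an iteration.
mesh_query_handle <- function(mesh) {
  list(ptr = cpp_mesh_handle(mesh$vertices, mesh$triangles),
       fn = face_normals(mesh))
}

# Internal: truncated-least-squares data term: a valid correspondence
# contributes its squared point-to-plane residual (mm), an invalid one (too
# far, or facing the wrong way) contributes the constant squared cutoff.
# The constant keeps the objective from rewarding poses that merely push
# mismatched points beyond the cutoff (the classic trimmed-ICP drift).
truncated_data_term <- function(co, cutoff) {
  r <- abs(rowSums((co$q - co$cp) * co$n))
  r[!co$valid] <- cutoff
  sum((1000 * r)^2)
}

# Internal: data-term residual pieces of one camera against a fixed mesh.
# Returns world points q, closest points, face normals at the closest
# triangles, and the validity mask: Euclidean distance <= cutoff and, when
# the camera's normals are supplied, agreement between the point normal and
# the mesh normal (rejects correspondences onto an opposite-facing sheet).
mesh_correspondences <- function(points, pose, mh, cutoff, normals = NULL) {
  q <- transform_points(points, pose)
  cr <- cpp_closest_on_handle(mh$ptr, q)
  n <- mh$fn[cr$tri, , drop = FALSE]
  valid <- cr$dist <= cutoff
  if (!is.null(normals)) {
    wn <- transform_points(normals, pose, vectors = TRUE)
    valid <- valid & rowSums(wn * n) > 0
  }
  list(q = q, cp = cr$point, n = n, valid = valid, dist = cr$dist)
}

#' Per-camera objective against a fixed mesh
#'
#' The single-camera term of the global objective: squared point-to-plane
#' distances (in millimeters) from the camera's points to the closest mesh
#' point, with correspondences farther than the cutoff excluded, plus the
#' pose anchor Gamma.
#'
#' @param points n x 3 camera-frame points (normally the overlap subset).
#' @param pose current camera pose.
#' @param pose0 calibrated initial pose.
#' @param mesh the fixed global [tri_mesh()].
#' @param cfg a [registration_config()].
#' @param normals optional camera-frame unit normals of `points`; when given,
#'   correspondences whose mesh normal opposes the point normal are excluded.
#' @return Scalar objective value (mm^2 units for the data term).
#' @export
camera_objective <- function(points, pose, pose0, mesh, cfg = registration_config(),
                             normals = NULL) {
  mh <- if (is.list(mesh) && !is.null(mesh$ptr)) mesh else mesh_query_handle(mesh)
  w <- regularizer_weights(cfg$kr, cfg$kt)
  co <- mesh_correspondences(points, pose, mh, cfg$cutoff, normals)
  truncated_data_term(co, cfg$cutoff) + gamma_regularizer(pose, pose0, w)
}

#' Align one camera to the global mesh
#'
#' Gauss-Newton minimization of the six pose-increment parameters of the
#' per-camera objective: point-to-plane residuals to the closest mesh point
#' (normal taken from the closest triangle), correspondences beyond the
#' cutoff excluded, plus the pose anchor Gamma. Correspondences are
#' recomputed every inner step, a halving line search enforces monotone
#' descent, and the returned pose is re-orthonormalized.
#'
#' @param points n x 3 camera-frame points (the camera's overlap subset).
#' @param Ti current pose.
#' @param Ti0 calibrated initial pose.
#' @param M the fixed global [tri_mesh()].
#' @param cfg a [registration_config()].
#' @param normals optional camera-frame unit normals of `points` for the
#'   normal-agreement correspondence filter.
#' @return The updated [rigid_transform()], with attributes `objective`
#'   (final value), `evals` (objective evaluations used) and `n_valid`.
#'   With fewer than 6 valid correspondences the pose is returned unchanged
#'   with a warning.
#' @export
align_camera_to_mesh <- function(points, Ti, Ti0, M, cfg = registration_config(),
                                 normals = NULL) {
  mh <- if (is.list(M) && !is.null(M$ptr)) M else mesh_query_handle(M)
  w <- regularizer_weights(cfg$kr, cfg$kt)
  evals <- 0L
  obj <- function(pose) {
    evals <<- evals + 1L
    co <- mesh_correspondences(points, pose, mh, cfg$cutoff, normals)
    truncated_data_term(co, cfg$cutoff) + gamma_regularizer(pose, Ti0, w)
  }
  pose <- as_rigid_transform(Ti)
  E <- obj(pose)
  n_valid <- NA_integer_
  for (inner in seq_len(cfg$max_inner)) {
    co <- mesh_correspondences(points, pose, mh, cfg$cutoff, normals)
    n_valid <- sum(co$valid)
    if (n_valid < 6) {
      warning("fewer than 6 valid correspondences; pose left unchanged")
      out <- as_rigid_transform(Ti)
      attr(out, "objective") <- E
      attr(out, "evals") <- evals
      attr(out, "n_valid") <- n_valid
      return(out)
    }
    q <- co$q[co$valid, , drop = FALSE]
    cp <- co$cp[co$valid, , drop = FALSE]
    nn <- co$n[co$valid, , drop = FALSE]
    r <- 1000 * rowSums((q - cp) * nn)
    qxn <- cbind(q[, 2] * nn[, 3] - q[, 3] * nn[, 2],
                 q[, 3] * nn[, 1] - q[, 1] * nn[, 3],
                 q[, 1] * nn[, 2] - q[, 2] * nn[, 1])
    J <- 1000 * cbind(qxn, nn)
    g0 <- gamma_residuals(pose, Ti0, w)
    Jg <- vapply(1:6, function(j) {
      h <- 1e-6
      e <- numeric(6)
      e[j] <- h
      (gamma_residuals(apply_increment(e, pose), Ti0, w) -
         gamma_residuals(apply_increment(-e, pose), Ti0, w)) / (2 * h)
    }, numeric(6))
    H <- crossprod(J) + crossprod(Jg)
    # Levenberg damping: the data constrains motion along surface normals
    # strongly but tangential motion only through curvature features, so a
    # small isotropic stiffness keeps noise in the flat directions from
    # driving large slides
    H <- H + cfg$lm_damping * mean(diag(H)) * diag(6)
    rhs <- -(crossprod(J, r) + t(Jg) %*% g0)
    delta <- tryCatch(solve(H, rhs), error = function(e) {
      message("singular normal system; damping applied")
      solve(H + 1e-6 * max(diag(H)) * diag(6), rhs)
    })
    # halving line search: never accept an increase
    lam <- 1
    improved <- FALSE
    for (try in 1:8) {
      cand <- apply_increment(lam * as.numeric(delta), pose)
      Ec <- obj(cand)
      if (Ec <= E) {
        pose <- cand
        E <- Ec
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    if (sqrt(sum((lam * delta)^2)) < cfg$step_tol) break
  }
  attr(pose, "objective") <- E
  attr(pose, "evals") <- evals
  attr(pose, "n_valid") <- n_valid
  pose
}

# Internal: mean absolute point-to-plane residual (mm) of the overlap points
# against a mesh, cutoff applied.
overlap_residual_mm <- function(rig, overlap, mesh, cutoff) {
  mh <- if (is.list(mesh) && !is.null(mesh$ptr)) mesh else mesh_query_handle(mesh)
  res <- unlist(lapply(seq_along(rig$cameras), function(i) {
    cam <- rig$cameras[[i]]
    if (length(overlap[[i]]) == 0) return(numeric(0))
    co <- mesh_correspondences(cam$points[overlap[[i]], , drop = FALSE],
                               cam$pose, mh, cutoff,
                               cam$normals[overlap[[i]], , drop = FALSE])
    abs(1000 * rowSums((co$q - co$cp) * co$n))[co$valid]
  }))
  mean(res)
}

# Internal: pooled world-frame oriented points of the whole rig, tagged by
# source camera so the reconstruction can vote across disagreeing clouds.
pooled_oriented_points <- function(rig) {
  pts <- do.call(rbind, lapply(rig$cameras, function(cam)
    transform_points(cam$points, cam$pose)))
  nrm <- do.call(rbind, lapply(rig$cameras, function(cam)
    transform_points(cam$normals, cam$pose, vectors = TRUE)))
  cl <- rep(seq_along(rig$cameras) - 1L,
            vapply(rig$cameras, function(cam) nrow(cam$points), integer(1)))
  oriented_points(pts, nrm, cloud = cl)
}

# Internal: quick estimate (mm -> meters) of the current cloud-to-cloud
# misalignment: mean nearest-neighbour distance of a subsample of each
# camera's overlap points to the union of the other cameras' points.
rig_misalignment <- function(rig, overlap, per_cam = 150) {
  world <- lapply(rig$cameras, function(cam) transform_points(cam$points, cam$pose))
  d <- unlist(lapply(seq_along(world), function(i) {
    if (length(overlap[[i]]) == 0) return(numeric(0))
    take <- overlap[[i]][seq(1, length(overlap[[i]]),
                             length.out = min(per_cam, length(overlap[[i]])))]
    cpp_knn(do.call(rbind, world[-i]), world[[i]][take, , drop = FALSE], 1)$dist[, 1]
  }))
  mean(d)
}

#' Interleaved camera-pose optimization
#'
#' Alternates two steps until the residual stabilizes or `max_iter` is
#' reached: (1) rebuild the global surface M from all cameras' world-frame
#' points and normals at the current poses (reconstruction depth
#' `depth_intermediate`); (2) align every camera to M with
#' [align_camera_to_mesh()]. Overlap sets are computed once from the initial
#' poses. The mean absolute point-to-plane residual of the overlap points
#' (mm) is recorded per iteration; the first trace entry is the residual at
#' the initial poses against the first mesh. The final surface is rebuilt at
#' `depth_final`.
#'
#' @param rig a [camera_rig()] with poses initialized from calibration.
#' @param cfg a [registration_config()].
#' @param verbose print per-iteration residuals.
#' @param final_mesh rebuild the final surface at `depth_final` (switch off
#'   when only the refined poses and residual trace are needed).
#' @return List with `rig` (updated poses), `poses`, `mesh` (final surface),
#'   `trace` (residuals in mm, length iterations + 1), `iterations`, and
#'   `evals` (objective evaluations spent in the aligners).
#' @export
run_interleaved <- function(rig, cfg = registration_config(), verbose = FALSE,
                            final_mesh = TRUE) {
  overlap <- compute_overlap(rig, cfg$overlap_threshold)
  trace <- numeric(0)
  evals <- 0L
  iterations <- 0L
  cell_fixed <- NULL
  band_fixed <- cfg$band
  for (iter in seq_len(cfg$max_iter)) {
    op <- pooled_oriented_points(rig)
    if (is.null(cell_fixed)) {
      extent <- max(apply(op$points, 2, function(x) diff(range(x))))
      cell_fixed <- extent / 2^cfg$depth_intermediate
      if (is.null(band_fixed)) {
        nn2 <- cpp_knn(op$points, op$points[seq(1, nrow(op$points),
                                                length.out = 2000), , drop = FALSE], 2)
        band_fixed <- max(3 * cell_fixed, 2.5 * stats::median(nn2$dist[, 2]))
      }
    }
    M <- reconstruct_surface(op, depth = cfg$depth_intermediate, band = band_fixed,
                             trim_quantile = 0, cell = cell_fixed,
                             normals = FALSE)
    mh <- mesh_query_handle(M)
    if (iter == 1)
      trace <- overlap_residual_mm(rig, overlap, mh, cfg$cutoff)
    for (i in seq_along(rig$cameras)) {
      cam <- rig$cameras[[i]]
      if (length(overlap[[i]]) == 0) next
      sel <- overlap[[i]]
      if (length(sel) > cfg$max_align_points)
        sel <- sel[round(seq(1, length(sel), length.out = cfg$max_align_points))]
      pose <- align_camera_to_mesh(cam$points[sel, , drop = FALSE],
                                   cam$pose, cam$pose_init, mh, cfg,
                                   normals = cam$normals[sel, , drop = FALSE])
      evals <- evals + attr(pose, "evals")
      rig$cameras[[i]]$pose <- rigid_transform(pose$matrix)
    }
    iterations <- iter
    trace <- c(trace, overlap_residual_mm(rig, overlap, mh, cfg$cutoff))
    if (verbose)
      message(sprintf("[register] iteration %d: residual %.3f mm", iter,
                      trace[length(trace)]))
    if (abs(diff(tail(trace, 2))) <= cfg$conv_tol_mm) break
  }
  final <- if (final_mesh)
    reconstruct_surface(pooled_oriented_points(rig),
                        depth = cfg$depth_final, band = cfg$band,
                        trim_quantile = cfg$trim_quantile)
  list(rig = rig, poses = rig_poses(rig), mesh = final, trace = trace,
       iterations = iterations, evals = evals, overlap = overlap)
}

#' Residual metrics between the rig and a mesh
#'
#' Point-to-plane: mean over valid overlap points of the absolute distance
#' to the closest mesh point projected on that triangle's normal.
#' Point-to-point: mean nearest-neighbor distance from each camera's overlap
#' points to the union of the other cameras' points. Both in millimeters.
#'
#' @param rig a [camera_rig()].
#' @param mesh the global [tri_mesh()].
#' @param overlap overlap sets from [compute_overlap()]; computed at the
#'   current poses if missing.
#' @param cutoff valid-correspondence cutoff in meters.
#' @return List with `point_to_point` and `point_to_plane` (mm).
#' @export
residual_metrics <- function(rig, mesh, overlap = NULL, cutoff = 0.14) {
  if (is.null(overlap)) overlap <- compute_overlap(rig)
  p2plane <- overlap_residual_mm(rig, overlap, mesh, cutoff)
  world <- lapply(rig$cameras, function(cam) transform_points(cam$points, cam$pose))
  p2p <- unlist(lapply(seq_along(world), function(i) {
    if (length(overlap[[i]]) == 0) return(numeric(0))
    ref <- do.call(rbind, world[-i])
    d <- cpp_knn(ref, world[[i]][overlap[[i]], , drop = FALSE], 1)$dist[, 1]
    d[d <= cutoff]
  }))
  list(point_to_point = 1000 * mean(p2p), point_to_plane = p2plane)
}

#' Full cloud-to-cloud objective of a pose set
#'
#' The global objective evaluated without a reconstructed mesh: for every
#' overlap point the point-to-plane residual to its nearest neighbor in the
#' other cameras' clouds (using that neighbor's normal), squared in
#' millimeters, cutoff applied, plus the pose anchors. This is the
#' evaluation function shared by the population baseline and the
#' interleaved method when their solutions are compared, where rebuilding a
#' surface per candidate would be prohibitive.
#'
#' @param rig a [camera_rig()].
#' @param poses list of poses to evaluate (default: current).
#' @param overlap overlap sets (computed at initial poses if missing).
#' @param cfg a [registration_config()].
#' @return Scalar objective value.
#' @export
rig_objective <- function(rig, poses = NULL, overlap = NULL,
                          cfg = registration_config()) {
  if (!is.null(poses)) rig <- set_rig_poses(rig, poses)
  if (is.null(overlap)) overlap <- compute_overlap(rig, cfg$overlap_threshold)
  w <- regularizer_weights(cfg$kr, cfg$kt)
  world <- lapply(rig$cameras, function(cam) transform_points(cam$points, cam$pose))
  wnorm <- lapply(rig$cameras, function(cam)
    transform_points(cam$normals, cam$pose, vectors = TRUE))
  total <- 0
  for (i in seq_along(world)) {
    if (length(overlap[[i]]) == 0) next
    q <- world[[i]][overlap[[i]], , drop = FALSE]
    ref <- do.call(rbind, world[-i])
    rnm <- do.call(rbind, wnorm[-i])
    nn <- cpp_knn(ref, q, 1)
    valid <- nn$dist[, 1] <= cfg$cutoff
    p <- ref[nn$idx[, 1], , drop = FALSE]
    n <- rnm[nn$idx[, 1], , drop = FALSE]
    r <- abs(rowSums((q - p) * n))
    r[!valid] <- cfg$cutoff
    total <- total + sum((1000 * r)^2)
  }
  for (i in seq_along(rig$cameras))
    total <- total + gamma_regularizer(rig$cameras[[i]]$pose,
                                       rig$cameras[[i]]$pose_init, w)
  total
}

#' Elite-guided population minimizer
#'
#' Generic seeded stochastic optimizer: samples each generation from a
#' normal distribution clipped to the box, re-centers on the elite fraction
#' and shrinks the sampling spread toward it (cross-entropy style), with
#' elitism. Deterministic given the seed.
#'
#' @param fn objective function of a numeric vector.
#' @param half half-widths of the symmetric search box (length = dimension).
#' @param population samples per generation (>= 4).
#' @param iterations generations.
#' @param seed RNG seed.
#' @param elite_frac fraction of each generation guiding the next.
#' @return List with `par`, `value`, `trace` (best value per generation) and
#'   `evals`.
#' @export
cem_minimize <- function(fn, half, population = 1000, iterations = 50,
                         seed = 1, elite_frac = 0.1) {
  if (population < 4) stop("population must be at least 4")
  d <- length(half)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mu <- numeric(d)
  sigma <- half / 2
  best_xi <- mu
  best_val <- fn(best_xi)
  evals <- 1L
  n_elite <- max(2L, ceiling(elite_frac * population))
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    X <- matrix(rnorm(population * d, mean = rep(mu, each = population),
                      sd = rep(sigma, each = population)),
                population, d)
    X <- pmax(pmin(X, rep(half, each = population)), rep(-half, each = population))
    X[1, ] <- best_xi  # elitism: never lose the incumbent
    vals <- apply(X, 1, fn)
    evals <- evals + population
    ord <- order(vals)
    if (vals[ord[1]] < best_val) {
      best_val <- vals[ord[1]]
      best_xi <- X[ord[1], ]
    }
    elite <- X[ord[seq_len(n_elite)], , drop = FALSE]
    mu <- colMeans(elite)
    sigma <- pmax(apply(elite, 2, sd), half * 1e-4)
    trace[it] <- best_val
  }
  list(par = best_xi, value = best_val, trace = trace, evals = evals)
}

#' Population-based global pose optimization (baseline)
#'
#' A seeded elite-guided population optimizer (sampling with shrinking
#' covariance) over the pose parameters of all cameras but one, which stays
#' fixed; each non-fixed camera contributes six parameters bounded by the
#' given rotation/translation box around its initial pose. Serves as the
#' global-search comparator for the interleaved method; it evaluates the
#' same cloud-to-cloud objective ([rig_objective()]).
#'
#' @param rig a [camera_rig()].
#' @param rot_bound_deg,trans_bound per-parameter search bounds: rotations
#'   within +/- this many degrees, translations within +/- this many meters
#'   (defaults 3 degrees and 0.1 m).
#' @param population samples per generation (>= 4).
#' @param iterations generations.
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param fixed_camera index (1-based) of the camera held at its initial
#'   pose.
#' @param cfg a [registration_config()].
#' @param elite_frac fraction of each generation guiding the next.
#' @return List with `poses`, `objective`, `trace` (best objective per
#'   generation), `evals` and `xi` (best parameter vector).
#' @export
optimize_population_baseline <- function(rig, rot_bound_deg = 3, trans_bound = 0.1,
                                         population = 1000, iterations = 50,
                                         seed = 1, fixed_camera = 1,
                                         cfg = registration_config(),
                                         elite_frac = 0.1) {
  ncam <- length(rig$cameras)
  free <- setdiff(seq_len(ncam), fixed_camera)
  half <- rep(c(rep(rot_bound_deg * pi / 180, 3), rep(trans_bound, 3)), length(free))
  overlap <- compute_overlap(rig, cfg$overlap_threshold)
  poses_of <- function(xi) {
    poses <- rig_poses(rig, "init")
    for (j in seq_along(free)) {
      k <- free[j]
      poses[[k]] <- apply_increment(xi[(6 * j - 5):(6 * j)], poses[[k]])
    }
    poses
  }
  evaluate <- function(xi) rig_objective(rig, poses_of(xi), overlap, cfg)
  res <- cem_minimize(evaluate, half, population = population,
                      iterations = iterations, seed = seed,
                      elite_frac = elite_frac)
  list(poses = poses_of(res$par), objective = res$value, trace = res$trace,
       evals = res$evals, xi = res$par)
}

#' Pose errors against ground truth
#'
#' Rotation (degrees) and translation (meters) error of each estimated
#' camera pose. Because the data term of the registration objective is
#' invariant to a common rigid motion of all cameras (the anchor fixes the
#' gauge only softly, toward the noisy calibration), accuracy is assessed
#' after removing the best-fit common rigid motion mapping the estimated
#' camera centers onto the true ones, the standard practice for multi-view
#' registration benchmarks. Set `align_gauge = FALSE` for raw errors.
#'
#' @param poses_est,poses_true lists of [rigid_transform()].
#' @param align_gauge remove the best common rigid motion first (needs >= 3
#'   cameras).
#' @return List with vectors `rot_deg`, `trans_m`, and `gauge` (the removed
#'   common motion, or NULL).
#' @export
pose_errors <- function(poses_est, poses_true, align_gauge = TRUE) {
  stopifnot(length(poses_est) == length(poses_true))
  gauge <- NULL
  if (align_gauge && length(poses_est) >= 3) {
    c_est <- t(vapply(poses_est, translation, numeric(3)))
    c_true <- t(vapply(poses_true, translation, numeric(3)))
    if (max(dist(c_true)) > 1e-6) {  # degenerate center sets carry no gauge
      gauge <- kabsch_transform(c_est, c_true)
      poses_est <- lapply(poses_est, function(T) compose_transforms(gauge, T))
    }
  }
  rot <- vapply(seq_along(poses_est), function(i)
    rotation_angle_deg(rotation(poses_est[[i]]), rotation(poses_true[[i]])),
    numeric(1))
  trans <- vapply(seq_along(poses_est), function(i)
    sqrt(sum((translation(poses_est[[i]]) - translation(poses_true[[i]]))^2)),
    numeric(1))
  list(rot_deg = rot, trans_m = trans, gauge = gauge)
}
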