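# Overlap sets, Gauss-Newton alignment, the interleaved loop, metrics and
# the population baseline.

test_that("overlap membership matches a brute-force scan", {
  rig <- toy_rig(n_per = 120, seed = 2)
  ov <- compute_overlap(rig, threshold = 0.03)
  world <- lapply(rig$cameras, function(cam) transform_points(cam$points, cam$pose))
  for (i in 1:3) {
    ref <- do.call(rbind, world[-i])
    d <- oracle_nn_dist(ref, world[[i]])
    expect_equal(ov[[i]], which(d <= 0.03))
  }
  # co-located identical clouds overlap fully; distant clouds not at all
  twin <- camera_rig(list(
    list(pose_init = rigid_transform(), points = world[[1]], normals = rig$cameras[[1]]$normals),
    list(pose_init = rigid_transform(), points = world[[1]], normals = rig$cameras[[1]]$normals)))
  ov2 <- compute_overlap(twin, 0.01)
  expect_length(ov2[[1]], nrow(world[[1]]))
  apart <- twin
  apart$cameras[[2]]$points <- apart$cameras[[2]]$points + 1
  w <- testthat::capture_warnings(ov3 <- compute_overlap(apart, 0.01))
  expect_true(all(grepl("empty overlap", w)))
  expect_length(w, 2)
  expect_length(ov3[[1]], 0)
})

test_that("alignment leaves a pose already on the mesh unchanged", {
  sph <- fib_sphere(3000)
  mesh <- reconstruct_surface(oriented_points(sph$points, sph$normals), depth = 6)
  cloud <- mesh$vertices[seq(1, nrow(mesh$vertices), 17), ]  # sampled from M
  T0 <- rigid_transform()
  pose <- align_camera_to_mesh(cloud, T0, T0, mesh, registration_config(kr = 0, kt = 0))
  expect_lt(norm(pose$matrix - diag(4), "F"), 1e-5)
})

test_that("alignment recovers a 2 cm offset to millimeter accuracy", {
  sph <- fib_sphere(4000)
  mesh <- reconstruct_surface(oriented_points(sph$points, sph$normals), depth = 7)
  cloud <- sph$points[seq(1, 4000, 4), ]
  m <- diag(4); m[1, 4] <- 0.02
  pose <- align_camera_to_mesh(cloud, rigid_transform(m), rigid_transform(m), mesh,
                               registration_config(kr = 0, kt = 0, max_inner = 20),
                               normals = sph$normals[seq(1, 4000, 4), ])
  expect_lt(sqrt(sum(translation(pose)^2)), 0.001)
})

test_that("a dominant regularizer pins the pose to the anchor", {
  sph <- fib_sphere(2000)
  mesh <- reconstruct_surface(oriented_points(sph$points, sph$normals), depth = 6)
  cloud <- sph$points[seq(1, 2000, 4), ] + 0.01
  m <- diag(4); m[1:3, 4] <- c(0.02, 0, 0)
  Ti0 <- rigid_transform(m)
  # the data term is in squared millimeters, so the overwhelming-anchor
  # limit needs weights 1e6 times larger than on a squared-meter scale
  pose <- align_camera_to_mesh(cloud, Ti0, Ti0, mesh,
                               registration_config(kr = 1e15, kt = 1e15))
  expect_lt(norm(pose$matrix - Ti0$matrix, "F"), 1e-6)
})

test_that("with too few valid correspondences the pose is returned unchanged", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  cloud <- matrix(5, 4, 3)  # all beyond the cutoff
  T0 <- rigid_transform()
  expect_warning(pose <- align_camera_to_mesh(cloud, T0, T0, mesh), "fewer than 6")
  expect_equal(pose$matrix, diag(4))
})

test_that("Gauss-Newton inner steps never increase the objective", {
  sph <- fib_sphere(1500)
  mesh <- reconstruct_surface(oriented_points(sph$points, sph$normals), depth = 6)
  set.seed(31)
  for (k in 1:5) {
    xi <- c(runif(3, -0.02, 0.02), runif(3, -0.02, 0.02))
    T0 <- apply_increment(xi, rigid_transform())
    cloud <- sph$points[seq(1, 1500, 3), ]
    cfg <- registration_config(kr = 10, kt = 10)
    pose <- align_camera_to_mesh(cloud, T0, T0, mesh, cfg)
    e_before <- camera_objective(cloud, T0, T0, mesh, cfg)
    e_after <- attr(pose, "objective")
    expect_lte(e_after, e_before + 1e-9)
  }
})

test_that("kr = kt = 0 single camera against a fixed mesh is point-to-plane ICP", {
  set.seed(13)
  depth <- matrix(2 + 0.15 * matrix(rnorm(81), 9, 9), 9, 9)
  K <- camera_intrinsics(fx = 9, fy = 9, width = 9, height = 9)
  mesh <- triangulate_grid(backproject(depth, K))
  # 200 points sampled exactly on mesh faces: both solvers must find the
  # zero-residual optimum, so their converged objectives must agree
  tris <- mesh$triangles[rep(seq_len(nrow(mesh$triangles)), length.out = 200), ]
  b <- matrix(runif(600), ncol = 3)
  b <- b / rowSums(b)
  cloud <- b[, 1] * mesh$vertices[tris[, 1], ] +
    b[, 2] * mesh$vertices[tris[, 2], ] + b[, 3] * mesh$vertices[tris[, 3], ]
  m <- diag(4); m[1:3, 4] <- c(0.01, -0.005, 0.008)
  cfg <- registration_config(kr = 0, kt = 0, max_inner = 40, lm_damping = 0)
  pose <- align_camera_to_mesh(cloud, rigid_transform(m), rigid_transform(m), mesh, cfg)
  icp <- oracle_icp(cloud, m, mesh)
  expect_lt(abs(attr(pose, "objective") - icp$objective), 1e-6)
  expect_lt(norm(pose$matrix - icp$T, "F"), 1e-4)
})

test_that("the interleaved loop is a fixed point at truth and reduces residuals", {
  inst <- simulate_instance(seed = 77, width = 120, height = 90,
                            rot_max_deg = 0, trans_max = 0, depth_sigma = 0,
                            dropout = 0, fence = FALSE)
  reg <- run_interleaved(inst$rig, registration_config(max_iter = 4),
                         final_mesh = FALSE)
  err <- pose_errors(reg$poses, rig_poses(inst$rig, "true"))
  # the fixed point is held to within the consensus-mesh discretization bias
  # (a few mm at this render resolution)
  expect_lt(mean(err$rot_deg), 0.3)
  expect_lt(mean(err$trans_m), 0.008)
  expect_lte(reg$trace[length(reg$trace)], reg$trace[1] * 1.05)
})

test_that("residual metrics follow their definitions on a plane", {
  g <- as.matrix(expand.grid(x = seq(-0.5, 0.5, by = 0.025),
                             y = seq(-0.5, 0.5, by = 0.025)))
  plane_pts <- cbind(g, 0)
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(g)), ncol = 3)
  mesh <- reconstruct_surface(oriented_points(plane_pts, nrm), depth = 6)
  d <- 0.004
  rig <- camera_rig(list(
    list(pose_init = rigid_transform(), points = cbind(g, d), normals = nrm),
    list(pose_init = rigid_transform(), points = plane_pts, normals = nrm)))
  ov <- compute_overlap(rig, 0.05)
  met <- residual_metrics(rig, mesh, ov)
  # camera 1 sits d above the plane mesh: its point-to-plane residual is ~d
  expect_lt(abs(met$point_to_plane - 1000 * d / 2), 1)
  expect_lte(met$point_to_plane, met$point_to_point + 1e-9)
})

test_that("point-to-plane is below point-to-point on jittered planes", {
  g <- as.matrix(expand.grid(x = seq(-0.4, 0.4, by = 0.02),
                             y = seq(-0.4, 0.4, by = 0.02)))
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(g)), ncol = 3)
  mesh <- reconstruct_surface(oriented_points(cbind(g, 0), nrm), depth = 6)
  wins <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    rig <- camera_rig(list(
      list(pose_init = rigid_transform(), points = cbind(g, rnorm(nrow(g), sd = 0.001)),
           normals = nrm),
      list(pose_init = rigid_transform(), points = cbind(g + 0.01, rnorm(nrow(g), sd = 0.001)),
           normals = nrm)))
    ov <- compute_overlap(rig, 0.05)
    met <- residual_metrics(rig, mesh, ov)
    if (met$point_to_plane < met$point_to_point) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("the population optimizer solves a convex box problem and is deterministic", {
  res <- cem_minimize(function(x) sum(x^2), half = rep(1, 12),
                      population = 200, iterations = 50, seed = 4)
  expect_lt(res$value, 1e-3)
  res2 <- cem_minimize(function(x) sum(x^2), half = rep(1, 12),
                       population = 200, iterations = 50, seed = 4)
  expect_identical(res$trace, res2$trace)
  expect_error(cem_minimize(function(x) sum(x^2), rep(1, 3), population = 3),
               "population")
})

test_that("gauge-aligned pose errors remove a common rigid motion", {
  rig <- toy_rig(n_per = 60, seed = 3)
  truth <- rig_poses(rig, "true")
  m <- diag(4)
  m[1:3, 1:3] <- rotation_about_axis(c(1, 1, 0), 0.3)
  m[1:3, 4] <- c(0.5, -0.2, 0.9)
  moved <- lapply(truth, function(T) compose_transforms(rigid_transform(m), T))
  err <- pose_errors(moved, truth)
  expect_lt(max(err$rot_deg), 1e-5)
  expect_lt(max(err$trans_m), 1e-9)
  raw <- pose_errors(moved, truth, align_gauge = FALSE)
  expect_gt(min(raw$rot_deg), 10)
})
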