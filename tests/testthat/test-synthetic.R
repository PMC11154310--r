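# Scene simulator: determinism, camera geometry, rendering and degradation.

small_cfg <- function(w = 80, h = 60, ...)
  scene_config(K = scale_intrinsics(camera_intrinsics(), w, h), ...)

test_that("the same seed reproduces the scene exactly", {
  a <- generate_scene(small_cfg(), seed = 9)
  b <- generate_scene(small_cfg(), seed = 9)
  expect_identical(a$animal$vertices, b$animal$vertices)
  expect_identical(lapply(a$cameras, function(c) c$pose$matrix),
                   lapply(b$cameras, function(c) c$pose$matrix))
  c2 <- generate_scene(small_cfg(), seed = 10)
  expect_false(identical(a$animal$vertices, c2$animal$vertices))
})

test_that("cameras sit on the ring with even angular spacing, aimed inward", {
  scene <- generate_scene(small_cfg(), seed = 1)
  centers <- t(vapply(scene$cameras, function(c) translation(c$pose), numeric(3)))
  ang <- atan2(centers[, 2], centers[, 1])
  gaps <- sort((diff(c(ang, ang[1] + 2 * pi)) * 180 / pi) %% 360)
  expect_equal(gaps, rep(36, 10), tolerance = 1e-9)
  expect_equal(sqrt(centers[, 1]^2 + centers[, 2]^2), rep(2, 10), tolerance = 1e-12)
  for (cam in scene$cameras) {
    fwd <- rotation(cam$pose)[, 3]
    to_target <- c(0, 0, 0.8) - translation(cam$pose)
    expect_gt(sum(fwd * to_target) / sqrt(sum(to_target^2)), 0.999)
  }
})

test_that("the animal mesh is closed (no boundary half-edges)", {
  scene <- generate_scene(small_cfg(), seed = 4)
  expect_length(find_boundary_loops(scene$animal), 0)
})

test_that("ray-cast depth hits the right surfaces with the right labels", {
  scene <- generate_scene(small_cfg(), seed = 1)
  r <- render_depth(scene, 1)
  K <- scene$cameras[[1]]$K
  # the principal ray points at the animal's center: label animal, plausible depth
  pv <- round(K$cy) + 1; pu <- round(K$cx) + 1
  expect_equal(r$label[pv, pu], 1)
  d_expect <- sqrt(sum((translation(scene$cameras[[1]]$pose) - c(0, 0, 0.8))^2))
  expect_lt(r$depth[pv, pu], d_expect)      # hits the body before its center
  expect_gt(r$depth[pv, pu], 0.1)
  # without the animal the same ray reaches the environment or nothing
  r2 <- render_depth(scene, 1, include_animal = FALSE)
  expect_true(is.na(r2$label[pv, pu]) || r2$label[pv, pu] == 0)
  # fence bars occlude: some rays that would hit the animal return environment
  with_bars <- sum(r$label == 0 & !is.na(r$label))
  expect_gt(with_bars, 0)
})

test_that("perturbations stay inside their bounds and are deterministic", {
  scene <- generate_scene(small_cfg(), seed = 2)
  caps <- perturb_and_degrade(scene, rot_max_deg = 3, trans_max = 0.1, seed = 11)
  caps2 <- perturb_and_degrade(scene, rot_max_deg = 3, trans_max = 0.1, seed = 11)
  expect_identical(caps$cameras[[3]]$depth, caps2$cameras[[3]]$depth)
  for (cam in caps$cameras) {
    rel <- compose_transforms(invert_transform(cam$pose_true), cam$pose_init)
    expect_lte(rotation_angle_deg(rotation(rel)), 3 * sqrt(3) + 1e-9)
    expect_lte(max(abs(translation(rel))), 0.1 + 1e-12)
  }
  # zero magnitudes leave the poses untouched
  caps0 <- perturb_and_degrade(scene, rot_max_deg = 0, trans_max = 0,
                               depth_sigma = 0, dropout = 0, seed = 3)
  for (cam in caps0$cameras)
    expect_equal(cam$pose_init$matrix, cam$pose_true$matrix)
})

test_that("depth noise has the requested magnitude on a flat region", {
  cfg <- small_cfg(120, 90)
  scene <- generate_scene(cfg, seed = 3)
  clean <- perturb_and_degrade(scene, depth_sigma = 0, dropout = 0, seed = 21)
  noisy <- perturb_and_degrade(scene, depth_sigma = 0.001, dropout = 0, seed = 21)
  diff <- noisy$cameras[[1]]$depth - clean$cameras[[1]]$depth
  s <- sd(diff[is.finite(diff)])
  expect_lt(abs(s - 0.001), 0.0001)
})

test_that("dropout removes about the requested fraction of pixels", {
  scene <- generate_scene(small_cfg(), seed = 3)
  drop <- perturb_and_degrade(scene, dropout = 0.1, depth_sigma = 0, seed = 8)
  keep <- perturb_and_degrade(scene, dropout = 0, depth_sigma = 0, seed = 8)
  n_keep <- sum(is.finite(keep$cameras[[1]]$depth))
  n_drop <- sum(is.finite(drop$cameras[[1]]$depth))
  expect_lt(abs(1 - n_drop / n_keep - 0.1), 0.02)
})

test_that("pixel labels are conserved through back-projection", {
  scene <- generate_scene(small_cfg(), seed = 6)
  caps <- perturb_and_degrade(scene, depth_sigma = 0, dropout = 0, seed = 1)
  cam <- caps$cameras[[2]]
  cloud <- backproject(cam$depth, cam$K, labels = cam$label)
  expect_identical(cloud$labels, as.vector(cam$label))
  mesh <- triangulate_grid(cloud)
  expect_equal(length(mesh$labels), nrow(mesh$vertices))
})
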