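# Oriented-point surface reconstruction and its quality statistics.

test_that("a sampled sphere reconstructs closed and accurate", {
  sph <- fib_sphere(5000)
  op <- oriented_points(sph$points, sph$normals)
  mesh <- reconstruct_surface(op, depth = 6)
  st <- mesh_stats(mesh)
  expect_true(st$watertight)
  expect_equal((st$euler - 2) %% 2, 0)  # 2 - 2g with integer genus
  d <- abs(sqrt(rowSums(mesh$vertices^2)) - 0.5)
  expect_lte(mean(d), 0.005)
})

test_that("deeper grids resolve more triangles", {
  sph <- fib_sphere(5000)
  op <- oriented_points(sph$points, sph$normals)
  n_tris <- vapply(c(5, 6, 7), function(d)
    nrow(reconstruct_surface(op, depth = d)$triangles), numeric(1))
  expect_true(all(diff(n_tris) > 0))
})

test_that("reconstruction error shrinks with depth at fixed sampling", {
  sph <- fib_sphere(20000)
  op <- oriented_points(sph$points, sph$normals)
  err <- vapply(c(5, 6, 7), function(d) {
    m <- reconstruct_surface(op, depth = d)
    mean(abs(sqrt(rowSums(m$vertices^2)) - 0.5))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("input guards fire", {
  sph <- fib_sphere(50)
  expect_error(reconstruct_surface(oriented_points(sph$points, sph$normals)),
               "at least 100")
  expect_error(oriented_points(sph$points, sph$normals * 0), "degenerate")
  expect_error(reconstruct_surface(oriented_points(fib_sphere(200)$points,
                                                   fib_sphere(200)$normals),
                                   depth = 15), "depth")
})

test_that("misaligned sheets of one surface blend into a single consensus", {
  # two copies of a plane patch offset by 30 mm along the normal: the
  # reconstruction should produce one sheet between them, not two
  set.seed(9)
  g <- as.matrix(expand.grid(x = seq(-0.5, 0.5, by = 0.02),
                             y = seq(-0.5, 0.5, by = 0.02)))
  pts <- rbind(cbind(g, 0), cbind(g, 0.03))
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
  mesh <- reconstruct_surface(oriented_points(pts, nrm), depth = 6, band = 0.05)
  z <- mesh$vertices[, 3]
  core <- abs(mesh$vertices[, 1]) < 0.4 & abs(mesh$vertices[, 2]) < 0.4
  expect_lt(max(abs(z[core] - 0.015)), 0.008)  # one mid-sheet
})

test_that("the animal body mesh obeys the closed-surface Euler relation", {
  cfg <- scene_config(K = scale_intrinsics(camera_intrinsics(), 80, 60))
  scene <- generate_scene(cfg, seed = 2)
  st <- mesh_stats(scene$animal)
  expect_true(st$watertight)
  expect_equal((st$euler - 2) %% 2, 0)
  expect_equal(st$euler, 2)  # genus 0
  expect_equal(st$triangles, 2 * st$vertices - 4)
})
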