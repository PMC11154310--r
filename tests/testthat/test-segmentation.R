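# Environment removal, long-edge filtering, boundary loops and erosion.

test_that("background removal matches a brute-force distance scan", {
  set.seed(21)
  mesh <- grid_patch(6, 6)
  env <- mesh$vertices[sample(36, 18), , drop = FALSE]
  env <- env + matrix(rnorm(nrow(env) * 3, sd = 0.004), ncol = 3)
  bg <- background_index(env, radius = 0.02)
  out <- remove_background(mesh, bg)
  near <- oracle_nn_dist(env, mesh$vertices) <= 0.02
  expect_equal(nrow(out$vertices), sum(!near))
  # identical frame and environment -> empty
  bg_all <- background_index(mesh$vertices, radius = 0.02)
  expect_equal(nrow(remove_background(mesh, bg_all)$vertices), 0)
  # environment far away -> unchanged
  bg_far <- background_index(mesh$vertices + 10, radius = 0.02)
  expect_equal(remove_background(mesh, bg_far)$vertices, mesh$vertices)
})

test_that("long-edge filtering uses the input mean, once", {
  mesh <- grid_patch(5, 5)        # near-equilateral: nothing removed
  expect_equal(nrow(remove_long_edges(mesh)$triangles), nrow(mesh$triangles))
  # stretch one vertex so its edges exceed twice the mean
  stretched <- mesh
  stretched$vertices[13, ] <- stretched$vertices[13, ] + c(0, 0, 10)
  out <- remove_long_edges(stretched)
  # oracle: recompute unique-edge statistics by hand
  e <- mesh_edges(stretched)
  len <- sqrt(rowSums((stretched$vertices[e[, 1], ] - stretched$vertices[e[, 2], ])^2))
  long <- e[len > 2 * mean(len), , drop = FALSE]
  bad <- apply(stretched$triangles, 1, function(tr)
    any(apply(long, 1, function(ed) all(ed %in% tr))))
  expect_equal(nrow(out$triangles), sum(!bad))
  # invariant: no surviving edge exceeds twice the input mean
  e2 <- mesh_edges(out)
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  len2 <- sqrt(rowSums((out$vertices[e2[, 1], ] - out$vertices[e2[, 2], ])^2))
  expect_true(all(len2 <= 2 * mean(len)))
  # empty mesh passes through
  empty <- tri_mesh(matrix(numeric(), ncol = 3), matrix(integer(), ncol = 3))
  expect_equal(nrow(remove_long_edges(empty)$triangles), 0)
})

test_that("boundary loops have the right combinatorics", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_length(find_boundary_loops(tet), 0)
  single <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  loops <- find_boundary_loops(single)
  expect_length(loops, 1)
  expect_length(loops[[1]], 3)
  # grid patches: one loop around the perimeter
  for (r in c(2, 4, 8)) for (c in c(3, 4)) {
    loops <- find_boundary_loops(grid_patch(r, c))
    expect_length(loops, 1)
    expect_length(loops[[1]], 2 * (r - 1) + 2 * (c - 1))
  }
})

test_that("non-manifold edges are reported by name", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  tris <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(find_boundary_loops(tri_mesh(v, tris)), "non-manifold")
})

test_that("boundary erosion peels rings and is idempotent on closed meshes", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_equal(erode_boundary(tet, 5)$vertices, tet$vertices)
  single <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(nrow(erode_boundary(single, 1)$vertices), 0)
  # 4x4 grid, one round: only the 2x2 interior block survives (2 triangles)
  out <- erode_boundary(grid_patch(4, 4), 1)
  expect_equal(nrow(out$vertices), 4)
  expect_equal(nrow(out$triangles), 2)
  # oracle: manual removal of perimeter vertices gives the same set
  mesh <- grid_patch(4, 4)
  rim <- unique(unlist(find_boundary_loops(mesh)))
  manual <- mesh_subset_vertices(mesh, setdiff(seq_len(16), rim))
  expect_equal(sort(as.vector(out$vertices)), sort(as.vector(manual$vertices)))
  # once no boundary remains nothing changes (closed -> idempotent)
  expect_equal(erode_boundary(tet, 1)$triangles, erode_boundary(tet, 3)$triangles)
})

test_that("segmentation isolates the animal on a simulated scene", {
  inst <- simulate_instance(seed = 401, width = 120, height = 90)
  ss <- attr(inst$rig, "seg_stats")
  expect_gte(1 - sum(ss$env_kept) / sum(ss$env_total), 0.99)
  expect_gte(sum(ss$animal_kept) / sum(ss$animal_total), 0.85)
  # segmentation never invents vertices: every kept point was captured
  cam <- inst$captures$cameras[[1]]
  cloud <- backproject(cam$depth, cam$K)
  pts <- inst$rig$cameras[[1]]$points
  all_pts <- cloud$points[as.vector(cloud$valid), ]
  expect_lt(max(oracle_nn_dist(all_pts, pts[1:50, , drop = FALSE])), 1e-12)
})

test_that("a scene without the animal raises a no-animal error", {
  cfg <- scene_config(K = scale_intrinsics(camera_intrinsics(), 80, 60))
  scene <- generate_scene(cfg, seed = 5)
  env_render <- render_depth(scene, 1, include_animal = FALSE)
  cloud <- backproject(env_render$depth, scene$cameras[[1]]$K)
  mesh <- triangulate_grid(cloud)
  bg <- background_index(cloud$points[as.vector(cloud$valid), ])
  expect_error(segment_cattle(mesh, bg), "no animal")
})
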