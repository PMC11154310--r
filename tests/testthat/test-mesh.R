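# Mesh container, statistics and exact point-to-mesh distances.

test_that("point_mesh_distance handles vertex, face and edge cases exactly", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(point_mesh_distance(c(0, 0, 0), mesh)$distance, 0)
  expect_equal(point_mesh_distance(c(0.25, 0.25, 0.5), mesh)$distance, 0.5)
  expect_equal(point_mesh_distance(c(2, 0, 0), mesh)$distance, 1)
  expect_error(point_mesh_distance(c(0, 0, 0),
                                   tri_mesh(matrix(0, 1, 3), matrix(integer(), ncol = 3))),
               "empty")
})

test_that("point_mesh_distance equals the exhaustive per-triangle oracle", {
  set.seed(11)
  depth <- matrix(2 + 0.2 * matrix(rnorm(64), 8, 8), 8, 8)
  K <- camera_intrinsics(fx = 8, fy = 8, width = 8, height = 8)
  mesh <- triangulate_grid(backproject(depth, K))
  expect_lte(nrow(mesh$triangles), 500)
  queries <- matrix(runif(40 * 3, -1.5, 2.5), ncol = 3)
  got <- point_mesh_distance(queries, mesh)$distance
  want <- apply(queries, 1, oracle_point_mesh_distance, mesh = mesh)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("mesh statistics and Euler characteristic are exact", {
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  st <- mesh_stats(tet)
  expect_equal(st$vertices, 4)
  expect_equal(st$triangles, 4)
  expect_true(st$watertight)
  expect_equal(st$euler, 2)
  single <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_false(mesh_stats(single)$watertight)
})

test_that("vertex normals are the normalized mean of incident face normals", {
  set.seed(3)
  depth <- matrix(2 + 0.05 * matrix(rnorm(25), 5, 5), 5, 5)
  K <- camera_intrinsics(fx = 5, fy = 5, width = 5, height = 5)
  mesh <- triangulate_grid(backproject(depth, K))
  fn <- face_normals(mesh)
  vn <- vertex_normals(mesh)
  for (v in sample(nrow(mesh$vertices), 8)) {
    inc <- which(apply(mesh$triangles == v, 1, any))
    avg <- colSums(fn[inc, , drop = FALSE])
    avg <- avg / sqrt(sum(avg^2))
    expect_equal(as.numeric(vn[v, ]), as.numeric(avg), tolerance = 1e-12)
  }
})

test_that("subsetting vertices reindexes and never adds vertices", {
  mesh <- grid_patch(4, 4)
  keep <- rep(TRUE, nrow(mesh$vertices))
  keep[1:4] <- FALSE
  sub <- mesh_subset_vertices(mesh, keep)
  expect_equal(nrow(sub$vertices), 12)
  expect_true(all(sub$triangles >= 1 & sub$triangles <= nrow(sub$vertices)))
  # every kept vertex position exists in the input
  expect_true(all(sub$vertices %in% mesh$vertices))
})

test_that("component filtering keeps large pieces and drops blobs", {
  a <- grid_patch(4, 4)
  b <- grid_patch(2, 2)
  b$vertices <- b$vertices + 100
  both <- tri_mesh(rbind(a$vertices, b$vertices),
                   rbind(a$triangles, b$triangles + nrow(a$vertices)))
  expect_equal(nrow(largest_component(both)$vertices), 16)
  expect_equal(nrow(keep_components(both, min_frac = 0.1)$vertices), 20)
  expect_equal(nrow(keep_components(both, min_frac = 0.5)$vertices), 16)
})

test_that("duplicate triangles and bad indices are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 3), c(2, 3, 1))), "duplicate")
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of range")
})
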