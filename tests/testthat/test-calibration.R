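# Sphere fitting and sphere-rig extrinsic calibration.

sphere_points <- function(center, r, n = 200, hemi = FALSE, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  if (hemi) v[, 3] <- abs(v[, 3])
  sweep(r * v, 2, center, "+")
}

# a rig of sphere centers with mutually distinct pairwise distances
test_rig_centers <- function() {
  # a meter-scale rig with pairwise distances mutually distinct by > 40 mm
  rbind(c(0.985, 0.364, 0.527), c(0.016, 1.109, 0.265),
        c(0.762, 1.269, 0.100), c(1.228, 0.321, 0.905),
        c(0.702, 1.286, 0.475), c(1.093, 0.805, 1.056))
}

test_that("sphere fitting is exact on noiseless data", {
  pts <- sphere_points(c(1, 2, 3), 0.1)
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center - c(1, 2, 3))), 1e-9)
  expect_lt(abs(fit$radius - 0.1), 1e-9)
  # hemisphere coverage only
  hemi <- sphere_points(c(-0.5, 0.2, 1.1), 0.08, hemi = TRUE, seed = 2)
  fit2 <- fit_sphere(hemi)
  expect_lt(max(abs(fit2$center - c(-0.5, 0.2, 1.1))), 1e-9)
  expect_lt(abs(fit2$radius - 0.08), 1e-9)
})

test_that("degenerate sphere input is rejected", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), "at least 4")
  flat <- cbind(matrix(rnorm(20), ncol = 2), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("sphere rigs register exactly without noise", {
  A <- test_rig_centers()
  expect_lt(norm(register_sphere_rig(A, A)$matrix - diag(4), "F"), 1e-9)
  m <- diag(4)
  m[1:3, 1:3] <- rotation_about_axis(c(1, -2, 0.5), 0.8)
  m[1:3, 4] <- c(0.4, -1.2, 0.7)
  G <- rigid_transform(m)
  B <- transform_points(A, invert_transform(G))
  got <- register_sphere_rig(A, B)
  expect_lt(norm(got$matrix - G$matrix, "F"), 1e-9)
  # invariance to the ordering of the input centers
  got2 <- register_sphere_rig(A, B[sample(nrow(B)), , drop = FALSE])
  expect_lt(norm(got2$matrix - G$matrix, "F"), 1e-9)
})

test_that("ambiguous pairwise distances raise an error", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(register_sphere_rig(sq, sq), "ambiguous")
})

test_that("calibration noise response stays within the design budget", {
  A <- test_rig_centers()
  m <- diag(4)
  m[1:3, 1:3] <- rotation_about_axis(c(0.3, 1, -0.2), -0.5)
  m[1:3, 4] <- c(-0.3, 0.8, 0.25)
  G <- rigid_transform(m)
  rot_err <- trans_err <- numeric(50)
  for (s in 1:50) {
    set.seed(1000 + s)
    Bnoisy <- transform_points(A, invert_transform(G)) +
      matrix(rnorm(length(A), sd = 0.001), ncol = 3)
    got <- register_sphere_rig(A, Bnoisy)
    rot_err[s] <- rotation_angle_deg(rotation(got), rotation(G))
    trans_err[s] <- sqrt(sum((translation(got) - translation(G))^2))
  }
  expect_lte(mean(rot_err), 0.1)
  expect_lte(mean(trans_err), 0.002)
})

test_that("chained calibration puts every camera in the first camera's frame", {
  A <- test_rig_centers()
  m <- diag(4)
  m[1:3, 1:3] <- rotation_about_axis(c(0, 0, 1), 1.2)
  m[1:3, 4] <- c(2, 0, 0)
  G2 <- rigid_transform(m)
  centers <- list(A, transform_points(A, invert_transform(G2)))
  poses <- calibrate_rig(centers)
  expect_equal(poses[[1]]$matrix, diag(4))
  expect_lt(norm(poses[[2]]$matrix - G2$matrix, "F"), 1e-9)
})
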