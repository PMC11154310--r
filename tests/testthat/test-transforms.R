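# Rigid-transform algebra, the small-angle linearization and the pose anchor.

test_that("identity and pure-translation increments behave exactly", {
  T0 <- rigid_transform()
  expect_equal(apply_increment(pose_increment(), T0)$matrix, diag(4))
  Tt <- apply_increment(pose_increment(t0 = 0.01), T0)
  expect_equal(translation(Tt), c(0.01, 0, 0))
  expect_equal(rotation(Tt), diag(3))
})

test_that("linearized rotation matches the exact rotation for small angles", {
  T1 <- apply_increment(pose_increment(alpha = 0.02), rigid_transform())
  exact <- rotation_about_axis(c(1, 0, 0), 0.02)
  expect_lt(norm(rotation(T1) - exact, "F"), 2e-4)
  # axis convention: beta about y, gamma about z
  T2 <- apply_increment(pose_increment(beta = 0.02), rigid_transform())
  expect_lt(norm(rotation(T2) - rotation_about_axis(c(0, 1, 0), 0.02), "F"), 2e-4)
  T3 <- apply_increment(pose_increment(gamma = 0.02), rigid_transform())
  expect_lt(norm(rotation(T3) - rotation_about_axis(c(0, 0, 1), 0.02), "F"), 2e-4)
})

test_that("extract_increment inverts the linearization", {
  expect_equal(as.numeric(extract_increment(rigid_transform())), rep(0, 6))
  m <- diag(4); m[1:3, 4] <- c(0.01, 0.02, 0.02)
  xi <- extract_increment(rigid_transform(m))
  expect_equal(as.numeric(xi), c(0, 0, 0, 0.01, 0.02, 0.02))
  m2 <- diag(4); m2[1:3, 1:3] <- rotation_about_axis(c(0, 0, 1), 0.01)
  xi2 <- extract_increment(rigid_transform(m2))
  expect_lt(abs(xi2[["gamma"]] - 0.01), 1e-6)
  expect_lt(max(abs(xi2[c(1, 2, 4, 5, 6)])), 1e-12)
})

test_that("extract_increment rejects rotations far from identity", {
  m <- diag(4); m[1:3, 1:3] <- rotation_about_axis(c(0, 0, 1), pi / 4)
  expect_error(extract_increment(rigid_transform(m)), "linearization")
})

test_that("apply/extract round-trip within tolerance for small motions", {
  set.seed(42)
  for (i in 1:25) {
    ang <- runif(3, -3, 3) * pi / 180
    tr <- runif(3, -0.1, 0.1)
    m <- diag(4)
    m[1:3, 1:3] <- rotation_about_axis(c(1, 0, 0), ang[1]) %*%
      rotation_about_axis(c(0, 1, 0), ang[2]) %*%
      rotation_about_axis(c(0, 0, 1), ang[3])
    m[1:3, 4] <- tr
    T_rel <- rigid_transform(m)
    back <- apply_increment(extract_increment(T_rel), rigid_transform())
    expect_lt(norm(back$matrix - T_rel$matrix, "F"), 1e-4)
  }
})

test_that("gamma matches its closed form and vanishes only at the anchor", {
  T0 <- rigid_transform()
  expect_equal(gamma_regularizer(T0, T0), 0)
  m <- diag(4); m[1:3, 4] <- c(0.01, 0.02, 0.02)
  expect_equal(gamma_regularizer(rigid_transform(m), T0, regularizer_weights(1, 1)),
               9e-4)
  m2 <- diag(4); m2[1:3, 1:3] <- rotation_about_axis(c(0, 0, 1), 0.01)
  # oracle: extract the parameters of the exact rotation, plug into the form
  g <- gamma_regularizer(rigid_transform(m2), T0, regularizer_weights(2, 1))
  xi <- extract_increment(rigid_transform(m2))
  expect_lt(abs(g - 2 * sum(xi[1:3]^2)), 1e-15)
  expect_lt(abs(g - 2e-4), 5e-8)
})

test_that("gamma is invariant to the absolute frame", {
  set.seed(7)
  m <- diag(4)
  m[1:3, 1:3] <- rotation_about_axis(runif(3), 0.03)
  m[1:3, 4] <- runif(3, -0.05, 0.05)
  Ti <- rigid_transform(m)
  Ti0 <- rigid_transform()
  g <- diag(4)
  g[1:3, 1:3] <- rotation_about_axis(c(1, 2, 3), 1.1)
  g[1:3, 4] <- c(5, -2, 1)
  G <- rigid_transform(g)
  w <- regularizer_weights(3, 7)
  expect_lt(abs(gamma_regularizer(compose_transforms(G, Ti), compose_transforms(G, Ti0), w) -
                gamma_regularizer(Ti, Ti0, w)), 1e-9)
})

test_that("non-finite increments and invalid matrices are rejected", {
  expect_error(pose_increment(alpha = NaN), "finite")
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(rigid_transform(bad), "orthonormal")
  bad2 <- diag(4); bad2[4, 1] <- 1e-4
  expect_error(rigid_transform(bad2), "last row")
})
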