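test_that("angle-axis rotations have Rodrigues semantics", {
  expect_equal(rotation_from_angle_axis(c(0, 0, 0)), diag(3))
  # half-turn about z flips x and y
  R <- rotation_from_angle_axis(c(0, 0, pi))
  expect_close(R %*% c(1, 0, 0), c(-1, 0, 0), 1e-12)
  expect_close(R %*% c(0, 1, 0), c(0, -1, 0), 1e-12)
  # orthogonality and unit determinant for random rotation vectors
  set.seed(42)
  for (i in 1:25) {
    p <- rnorm(3) * runif(1, 0, 4)
    R <- rotation_from_angle_axis(p)
    expect_close(t(R) %*% R, diag(3), 1e-12)
    expect_close(det(R), 1, 1e-12)
  }
})

test_that("angle-axis normalization is idempotent and preserves the rotation", {
  set.seed(7)
  for (i in 1:20) {
    p <- rnorm(3) * runif(1, 0, 10)
    q <- normalize_angle_axis(p)
    expect_lte(sqrt(sum(q^2)), pi + 1e-12)
    expect_close(normalize_angle_axis(q), q, 1e-12)
    expect_close(rotation_from_angle_axis(p), rotation_from_angle_axis(q), 1e-10)
  }
  expect_equal(normalize_angle_axis(c(0, 0, 0)), c(0, 0, 0))
})

test_that("site expansion satisfies the rigid reference-frame contract", {
  g <- water_geometry()
  s0 <- sites_from_pose(c(0, 0, 0, 0, 0, 0), g)
  # identity pose: O at origin, bisector along +z, molecule in xz-plane
  expect_close(s0["O", ], c(0, 0, 0), 1e-14)
  expect_close(s0["M", ], c(0, 0, g$r_om), 1e-12)
  expect_close(s0["H1", c(1, 3)], -s0["H2", c(1, 3)] * c(1, -1), 1e-12)
  expect_close(s0[, 2], rep(0, 4), 1e-14)
  expect_close(sqrt(sum(s0["H1", ]^2)), g$r_oh, 1e-12)
  ang <- acos(sum(s0["H1", ] * s0["H2", ]) / g$r_oh^2) * 180 / pi
  expect_close(ang, g$theta_hoh, 1e-8)

  # pure translation shifts every site
  tvec <- c(1.5, -2, 0.25)
  st <- sites_from_pose(c(tvec, 0, 0, 0), g)
  expect_close(st, s0 + matrix(tvec, 4, 3, byrow = TRUE), 1e-12)

  # rigidity: intramolecular distances are pose-independent
  d0 <- dist(s0)
  set.seed(3)
  for (i in 1:10) {
    pose <- c(rnorm(3) * 3, rnorm(3))
    expect_close(as.numeric(dist(sites_from_pose(pose, g))), as.numeric(d0),
                 1e-10)
  }
})

test_that("rotate-then-translate composition matches transforming identity sites", {
  g <- water_geometry()
  s0 <- sites_from_pose(rep(0, 6), g)
  set.seed(11)
  p <- rnorm(3); tvec <- rnorm(3) * 2
  R <- rotation_from_angle_axis(p)
  expect_close(sites_from_pose(c(tvec, p), g),
               t(R %*% t(s0)) + matrix(tvec, 4, 3, byrow = TRUE), 1e-12)
})

test_that("all_sites preserves order and counts", {
  cl <- rand_cluster(8, seed = 1)
  s <- all_sites(cl)
  expect_length(s, 8)
  expect_equal(unique(vapply(s, nrow, 0L)), 4L)
  cl1 <- water_cluster(matrix(c(1, 2, 3), 1, 3))
  expect_length(all_sites(cl1), 1)
  # permuting poses permutes the output identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  m <- as.matrix(cl)
  s2 <- all_sites(dcwater:::cluster_from_pose(m[perm, ]))
  for (k in seq_along(perm)) expect_equal(s2[[k]], s[[perm[k]]])
})
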