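test_that("O-O distance multisets: pair case, ideal cube, rigid-motion invariance", {
  two <- water_cluster(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(as.numeric(oo_distances(two)), 3)
  a <- 2.8
  cube <- ideal_cube(a, seed = 1)
  d <- sort(oo_distances(cube))
  expect_close(d, sort(c(rep(a, 12), rep(a * sqrt(2), 12), rep(a * sqrt(3), 4))),
               1e-12)
  set.seed(2)
  cl <- rand_cluster(5, seed = 3)
  R <- rotation_from_angle_axis(rnorm(3))
  moved <- dcwater:::transform_cluster(cl, R, rnorm(3) * 4)
  expect_close(sort(oo_distances(moved)), sort(oo_distances(cl)), 1e-9)
})

test_that("sorted-pairing RMSD equals the exhaustive permutation minimum (N = 4)", {
  for (s in 1:4) {
    a <- oo_distances(rand_cluster(4, seed = s))
    b <- oo_distances(rand_cluster(4, seed = 100 + s))
    expect_close(permutation_rmsd(a, b),
                 permutation_rmsd(a, b, method = "brute"), 1e-12)
  }
})

test_that("permutation RMSD: self-zero, closed form under scaling, pseudo-metric", {
  cl <- rand_cluster(6, seed = 8)
  d <- oo_distances(cl)
  expect_equal(permutation_rmsd(d, d), 0)
  # uniform scaling by (1+delta): RMSD = delta * sqrt(mean(R_i^2))
  delta <- 0.03
  expect_close(permutation_rmsd(d, d * (1 + delta)),
               delta * sqrt(mean(d^2)), 1e-12)
  # symmetry and triangle inequality on random triples
  for (s in 1:5) {
    x <- oo_distances(rand_cluster(5, seed = 200 + s))
    y <- oo_distances(rand_cluster(5, seed = 300 + s))
    z <- oo_distances(rand_cluster(5, seed = 400 + s))
    expect_close(permutation_rmsd(x, y), permutation_rmsd(y, x), 1e-14)
    expect_lte(permutation_rmsd(x, z),
               permutation_rmsd(x, y) + permutation_rmsd(y, z) + 1e-12)
  }
  expect_error(permutation_rmsd(oo_distances(rand_cluster(4, seed = 1)),
                                oo_distances(rand_cluster(5, seed = 1))),
               "equal size")
})

test_that("normalization options scale as P vs N", {
  d <- oo_distances(rand_cluster(5, seed = 77))
  e <- d + 0.1
  r_p <- permutation_rmsd(d, e)                       # divide by P = 10
  r_n <- permutation_rmsd(d, e, normalization = "n")  # divide by N = 5
  expect_close(r_n / r_p, sqrt(10 / 5), 1e-12)
})

test_that("d_max: pair distance and cube body diagonal", {
  expect_equal(d_max(water_cluster(rbind(c(0, 0, 0), c(3, 0, 0)))), 3)
  expect_close(d_max(ideal_cube(2.8, seed = 1)), 2.8 * sqrt(3), 1e-12)
})

test_that("average interacting count: closed ball, cube plateaus, endpoints, monotone steps", {
  a <- 2.8
  cube <- ideal_cube(a, seed = 2)
  expect_equal(avg_interacting(cube, 0.9 * a), 1)
  # between edge and face diagonal: 3 edge-neighbors + self
  expect_equal(avg_interacting(cube, 1.2 * a), 4)
  expect_equal(avg_interacting(cube, a), 4)  # tie at exactly r counts
  expect_equal(avg_interacting(cube, a * sqrt(3)), 8)
  cl <- rand_cluster(7, seed = 5)
  vals <- vapply(seq(0.5, d_max(cl) + 0.5, by = 0.05),
                 function(r) avg_interacting(cl, r), 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[1], 1)
  expect_equal(vals[length(vals)], 7)
})

test_that("shell radii fall in the distance gaps of ideal solids", {
  a <- 2.8
  cube <- ideal_cube(a, seed = 3)
  r1 <- shell_radii(cube)
  expect_gte(length(r1), 2)
  expect_true(any(r1 > a & r1 < a * sqrt(2)))
  expect_true(all(vapply(r1, function(r)
    avg_interacting(cube, r) %in% c(4, 7, 8), TRUE)))
  two <- water_cluster(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_length(shell_radii(two), 0)  # single distance, no interior gap
  # trigonal prism: distance multiset from direct enumeration
  pr <- ideal_prism(2.8, 2.6, seed = 4)
  d <- sort(oo_distances(pr))
  expect_close(d, sort(c(rep(2.8, 6), rep(2.6, 3),
                         rep(sqrt(2.8^2 + 2.6^2), 6))), 1e-12)
  expect_equal(permutation_rmsd(pr, pr), 0)
})
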