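# Oracles: every energy term is checked against an independent brute-force
# implementation in R over explicit site coordinates.

r_lj_oracle <- function(cl, p) {
  o <- t(vapply(all_sites(cl, p$geom), function(s) s["O", ], numeric(3)))
  e <- 0
  n <- nrow(o)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((o[i, ] - o[j, ])^2))
    e <- e + 4 * p$epsilon * ((p$sigma / d)^12 - (p$sigma / d)^6)
  }
  e
}

r_coulomb_oracle <- function(cl, p) {
  s <- all_sites(cl, p$geom)
  q <- c(H1 = p$q_h, H2 = p$q_h, M = p$q_m)
  e <- 0
  n <- length(s)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    for (a in names(q)) for (b in names(q)) {
      d <- sqrt(sum((s[[i]][a, ] - s[[j]][b, ])^2))
      e <- e + p$coulomb_k * q[[a]] * q[[b]] / d
    }
  e
}

molecular_dipole <- function(pose, p) {
  s <- sites_from_pose(pose, p$geom)
  p$q_h * s["H1", ] + p$q_h * s["H2", ] + p$q_m * s["M", ]
}

test_that("Lennard-Jones term: zero crossing, minimum, brute-force oracle", {
  p <- test_params()
  two <- function(d) water_cluster(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_close(lj_energy(two(p$sigma), p), 0, 1e-12)
  expect_close(lj_energy(two(2^(1/6) * p$sigma), p), -p$epsilon, 1e-12)
  for (s in 1:3) {
    cl <- rand_cluster(4, seed = s)
    expect_close(lj_energy(cl, p), r_lj_oracle(cl, p), 1e-10)
  }
})

test_that("Coulomb term matches a brute-force site-pair loop and has no intramolecular part", {
  p <- test_params()
  expect_equal(coulomb_energy(water_cluster(matrix(0, 1, 3)), p), 0)
  for (s in 1:3) {
    cl <- rand_cluster(3, seed = 10 + s)
    expect_close(coulomb_energy(cl, p), r_coulomb_oracle(cl, p), 1e-9)
  }
})

test_that("Coulomb energy approaches the point-dipole interaction at large separation", {
  p <- test_params()
  # parallel dipoles (identity orientations) so the leading term is nonzero
  p1 <- c(0, 0, 0, 0, 0, 0)
  for (d in c(50, 100, 200)) {
    p2 <- c(d, 0, 0, 0, 0, 0)
    cl <- dcwater:::cluster_from_pose(rbind(p1, p2))
    m1 <- molecular_dipole(p1, p)
    m2 <- molecular_dipole(p2, p)
    rhat <- c(1, 0, 0)
    e_dd <- p$coulomb_k *
      (sum(m1 * m2) - 3 * sum(m1 * rhat) * sum(m2 * rhat)) / d^3
    expect_close(coulomb_energy(cl, p) / e_dd, 1, 200 / d^2)
  }
})

test_that("static field: empty below contact, hand-summed for a pair, odd in the charges", {
  p <- test_params()
  cl <- dimer_cluster(2.9)
  expect_equal(static_field(cl, p, r = 1), matrix(0, 2, 3))
  # hand-summed point-charge field at molecule 1's M site
  s <- all_sites(cl, p$geom)
  m1 <- s[[1]]["M", ]
  q <- c(H1 = p$q_h, H2 = p$q_h, M = p$q_m)
  e_hand <- c(0, 0, 0)
  for (a in names(q)) {
    rv <- m1 - s[[2]][a, ]
    e_hand <- e_hand + q[[a]] * rv / sum(rv^2)^1.5
  }
  ef <- static_field(cl, p, r = 5)
  expect_close(ef[1, ], e_hand, 1e-12)
  # linearity: negating all charges negates every field vector
  pneg <- dc_params(q_h = -p$q_h, q_m = -p$q_m)
  expect_close(static_field(cl, pneg, r = 5), -ef, 1e-12)
})

test_that("induced dipoles: homogeneous limit, perturbative limit, solver agreement", {
  p <- test_params()
  cl <- dimer_cluster(2.9)
  # no neighbors -> zero field -> zero dipoles
  sol0 <- solve_induced_dipoles(cl, p, r = 1)
  expect_equal(sol0$mu, matrix(0, 2, 3))
  # alpha -> 0: mu -> alpha * e0 to first order
  psm <- dc_params(alpha = p$alpha * 1e-3)
  sol <- solve_induced_dipoles(cl, psm, r = 5)
  expect_close(sol$mu, psm$alpha * sol$e0, 1e-3 * max(abs(sol$mu)))
  # fixed point vs direct solve on random clusters
  pfp <- dc_params(scf_tol = 1e-13)
  for (s in 1:3) {
    cl5 <- local_minimize(rand_cluster(5, seed = 20 + s), pfp,
                          gtol = 1e-3)$cluster
    a <- solve_induced_dipoles(cl5, pfp, method = "direct")
    b <- solve_induced_dipoles(cl5, pfp, method = "fixed_point")
    expect_true(b$converged)
    expect_close(a$mu, b$mu, 1e-10)
  }
})

test_that("polarization energy: zero limits, sign, and the energy identity", {
  p <- test_params()
  expect_equal(polarization_energy(water_cluster(matrix(0, 1, 3)), p), 0)
  cl <- local_minimize(rand_cluster(5, seed = 2), p, gtol = 1e-3)$cluster
  expect_identical(polarization_energy(cl, p, r = 1), 0)
  epol <- polarization_energy(cl, p)
  expect_lte(epol, 0)
  sol <- solve_induced_dipoles(cl, p)
  expect_close(epol, -0.5 * p$coulomb_k * sum(sol$mu * sol$e0), 1e-10)
})

test_that("total energy: bookkeeping, cutoff-limit equivalence, frame invariance", {
  p <- test_params()
  cl <- local_minimize(rand_cluster(6, seed = 9), p, gtol = 1e-3)$cluster
  e <- total_energy(cl, p)
  expect_close(e$e_total, e$e_lj + e$e_coulomb + e$e_pol, 1e-10)
  # cutoff at/beyond d_max equals the uncutoff evaluation exactly
  efree <- total_energy(cl, p, cutoff = Inf)
  edm <- total_energy(cl, p, cutoff = d_max(cl))
  for (k in c("e_lj", "e_coulomb", "e_pol", "e_total"))
    expect_close(edm[[k]], efree[[k]], 1e-12)
  # below the closest contact the model is the pure pair potential
  esub <- total_energy(cl, p, cutoff = 0.99 * min(oo_distances(cl)))
  expect_identical(esub$e_pol, 0)
  expect_close(esub$e_total, esub$e_lj + esub$e_coulomb, 1e-12)
  # global rigid motions leave every term unchanged
  set.seed(33)
  for (i in 1:3) {
    R <- rotation_from_angle_axis(rnorm(3))
    tv <- rnorm(3) * 5
    e2 <- total_energy(dcwater:::transform_cluster(cl, R, tv), p)
    for (k in c("e_lj", "e_coulomb", "e_pol", "e_total"))
      expect_close(e2[[k]], e[[k]], 1e-9)
  }
})

test_that("cutoff semantics: neighbor relation and masked-pair monotonicity", {
  two <- function(d) water_cluster(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_true(neighbor_mask(two(2.8), 3)[1, 2])
  expect_false(neighbor_mask(two(2.8), 2.7)[1, 2])
  cl <- rand_cluster(7, seed = 4)
  expect_true(all(neighbor_mask(cl, d_max(cl))[upper.tri(diag(7))]))
  m <- neighbor_mask(cl, 3)
  expect_true(isSymmetric(m))
  expect_false(any(diag(m)))
  counts <- vapply(seq(1, 8, by = 0.25), function(r) sum(neighbor_mask(cl, r)), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("analytic gradient matches central finite differences", {
  p <- test_params()
  h <- 1e-5
  for (s in 1:2) {
    cl <- rand_cluster(4, seed = 40 + s)
    x <- as.matrix(cl)
    g <- energy_gradient(cl, p)
    gfd <- x * 0
    for (i in seq_len(nrow(x))) for (j in 1:6) {
      xp <- x; xm <- x
      xp[i, j] <- xp[i, j] + h
      xm[i, j] <- xm[i, j] - h
      gfd[i, j] <- (total_energy(dcwater:::cluster_from_pose(xp), p)$e_total -
                    total_energy(dcwater:::cluster_from_pose(xm), p)$e_total) / (2 * h)
    }
    expect_lt(max(abs(g - gfd) / (abs(gfd) + 1e-8)), 1e-5)
    # translation invariance: position gradients sum to zero
    expect_close(colSums(g[, 1:3]), c(0, 0, 0), 1e-8)
  }
})

test_that("degenerate configurations raise classed errors", {
  p <- test_params()
  overl <- water_cluster(rbind(c(0, 0, 0), c(0.05, 0, 0)))
  expect_error(lj_energy(overl, p), class = "degenerate_configuration")
  near <- water_cluster(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_error(total_energy(near, p), class = "degenerate_configuration")
})

test_that("charges-only induction mode drops the mutual coupling", {
  pm <- test_params()
  pc <- dc_params(mutual = FALSE)
  cl <- dimer_cluster(2.9)
  sol <- solve_induced_dipoles(cl, pc)
  expect_close(sol$mu, pc$alpha * sol$e0, 1e-14)
  # mutual induction changes (strengthens) the dipoles here
  solm <- solve_induced_dipoles(cl, pm)
  expect_gt(max(abs(solm$mu - sol$mu)), 1e-4)
})
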