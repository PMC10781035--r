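test_that("proposed moves perturb only the requested coordinates and respect the seed", {
  cl <- rand_cluster(5, seed = 1)
  m0 <- as.matrix(cl)
  expect_identical(as.matrix(propose_move(cl, "translational", 0)), m0)
  set.seed(5)
  mt <- as.matrix(propose_move(cl, "translational", 0.4))
  expect_identical(mt[, 4:6], m0[, 4:6])      # orientations untouched
  expect_true(all(abs(mt[, 1:3] - m0[, 1:3]) <= 0.4))
  set.seed(5)
  expect_identical(as.matrix(propose_move(cl, "translational", 0.4)), mt)
  set.seed(6)
  ma <- as.matrix(propose_move(cl, "angular", 0.3))
  expect_identical(ma[, 1:3], m0[, 1:3])
  expect_identical(as.matrix(cl), m0)         # input unmodified
})

test_that("quenches descend, converge, and are idempotent at a minimum", {
  p <- test_params()
  s <- bh_settings()
  for (sd in 1:3) {
    cl <- rand_cluster(4, seed = sd)
    e0 <- total_energy(cl, p)$e_total
    m <- local_minimize(cl, p, gtol = 1e-5, maxit = 2000)
    expect_lte(m$energy$e_total, e0)
    expect_true(m$converged)
    expect_lt(m$gmax, 1e-5)
    expect_lt(max(abs(energy_gradient(m$cluster, p))), 1e-5)
    # re-minimizing a stationary point leaves it essentially unchanged
    m2 <- local_minimize(m$cluster, p, gtol = 1e-5, maxit = 2000)
    expect_close(as.matrix(m2$cluster), as.matrix(m$cluster), 1e-5)
    expect_close(m2$energy$e_total, m$energy$e_total, 1e-10)
  }
})

test_that("dimer minimization reaches a seed-independent minimum", {
  p <- test_params()
  es <- vapply(1:20, function(s) {
    local_minimize(random_cluster(2, seed = s, container_radius = 3),
                   p, gtol = 1e-7, maxit = 3000)$energy$e_total
  }, 0)
  best <- min(es)
  # the global dimer minimum is found from most starts and is unique
  expect_gt(mean(abs(es - best) < 1e-6), 0.5)
  expect_lt(best, -4)  # bound hydrogen-bonded dimer
})

test_that("basin hopping is reproducible and its running best is monotone", {
  p <- test_params()
  s <- bh_settings(n_steps = 150, n_trajectories = 2, seed = 42)
  a <- basin_hopping(3, p, s)
  b <- basin_hopping(3, p, s)
  expect_identical(as.matrix(a$best), as.matrix(b$best))
  expect_identical(a$energy$e_total, b$energy$e_total)
  for (tr in a$trajectories)
    expect_true(all(diff(tr$best_history) <= 0))
})

test_that("two-molecule basin hopping finds the same dimer minimum from different seeds", {
  p <- test_params()
  e1 <- basin_hopping(2, p, bh_settings(n_steps = 150, n_trajectories = 1,
                                        seed = 7))$energy$e_total
  e2 <- basin_hopping(2, p, bh_settings(n_steps = 150, n_trajectories = 1,
                                        seed = 8))$energy$e_total
  expect_close(e1, e2, 1e-6)
})

test_that("step-size adaptation drives acceptance toward the target", {
  p <- test_params()
  fit <- basin_hopping(3, p, bh_settings(n_steps = 3000, n_trajectories = 1,
                                         seed = 3, target_acceptance = 0.2))
  acc <- fit$trajectories[[1]]$acceptance
  early <- mean(head(acc, 5))
  late <- mean(tail(acc, 10))
  expect_lt(abs(late - 0.2), abs(early - 0.2) + 0.25)
  # adapted steps moved away from their initial values
  expect_false(isTRUE(all.equal(tail(fit$trajectories[[1]]$step_trans, 1),
                                fit$settings$initial_translation_step)))
})
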