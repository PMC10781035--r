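# Shared fixtures for the test suite.  Everything is generated in code
# with fixed seeds; nothing is read from disk.

test_params <- function(...) dc_params(...)

# a compact random cluster that quenches without pathologies
rand_cluster <- function(n, seed, radius = 1.7 * n^(1/3)) {
  random_cluster(n, seed = seed, container_radius = radius)
}

# a near-linear hydrogen-bonded dimer pose (donor along +x), used where a
# physically reasonable (not pathological) two-molecule geometry is needed
dimer_cluster <- function(doo = 2.9) {
  water_cluster(rbind(c(0, 0, 0), c(doo, 0, 0)),
                rbind(c(0, -pi / 2 + 0.9, 0), c(0, pi / 2, 0)))
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max|diff| = %.3g < %.3g", max(abs(x - y)), tol))
}
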