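test_that("trajectories are bit-reproducible and seed-sensitive", {
  m <- flat_model()
  b <- bias_spec(1, 2000)
  t1 <- simulate_langevin(m, b, n_steps = 5000, dt = 0.01, seed = 7)
  t2 <- simulate_langevin(m, b, n_steps = 5000, dt = 0.01, seed = 7)
  t3 <- simulate_langevin(m, b, n_steps = 5000, dt = 0.01, seed = 8)
  expect_identical(t1$samples, t2$samples)
  expect_false(identical(t1$samples, t3$samples))
  ## thinning subsamples the same path
  t4 <- simulate_langevin(m, b, n_steps = 5000, dt = 0.01, seed = 7,
                          thin = 10)
  expect_identical(t4$samples, t1$samples[seq(1, 5001, by = 10)])
  expect_equal(t4$dt, 0.1)
})

test_that("zero diffusion freezes the dynamics", {
  m0 <- build_slab_model(
    pmf_params = c(list(well_depth = -2, plateau = 3), slab_geom),
    diff_params = list(d_vapor = 0, d_bulk = 0, transition_width = 0.25),
    density_params = slab_dens)
  for (metro in c(TRUE, FALSE)) {
    tr <- simulate_langevin(m0, bias_spec(1, 100), n_steps = 1000,
                            dt = 0.01, seed = 1, metropolis = metro)
    expect_true(all(tr$samples == 1))
  }
})

test_that("restrained window reproduces the OU stationary variance", {
  ## flat w, constant D, harmonic bias: var = kBT/k
  m <- flat_model()
  tr <- simulate_langevin(m, bias_spec(0, 2000), n_steps = 2e6, dt = 0.02,
                          seed = 42)
  expect_equal(var(tr$samples), kBT(300) / 2000, tolerance = 0.05)
  ## Metropolis correction keeps the proposal acceptance high
  expect_gt(tr$acceptance, 0.99)
})

test_that("stability guard rejects too-large time steps", {
  m <- flat_model(5e-3)
  expect_error(simulate_langevin(m, bias_spec(0, 2000), n_steps = 10,
                                 dt = 0.05, seed = 1), "time step too large")
  expect_error(simulate_langevin(m, bias_spec(0, 0), n_steps = 10,
                                 dt = 0.01, seed = 1, z0 = 10), "z0")
})

test_that("long-run histogram matches the Boltzmann density", {
  m <- small_dw_model()
  edges <- seq(-4, 4, by = 0.1)
  h <- sample_boltzmann_histogram(m, n_steps = 5e8, dt = 0.02, seed = 4,
                                  bin_edges = edges, z0 = 2)
  keep <- h$counts >= 2000
  expect_gt(sum(keep), 60)
  w_emp <- -kBT(300) * log(h$counts[keep])
  w_tru <- evaluate_model(m, h$mids[keep])$w
  dev <- (w_emp - mean(w_emp)) - (w_tru - mean(w_tru))
  expect_lt(sqrt(mean(dev^2)), 0.2)
})

test_that("non-constant D with flat w samples uniformly (D-gradient drift)", {
  ## regression against a missing D'(z) drift term: the buggy dynamics
  ## would follow 1/D, i.e. a 2.5x vapor/bulk occupancy imbalance, while
  ## the correct dynamics are uniform. Region-exchange noise on one run
  ## of this length is ~8%, far below the 150% failure signature.
  m <- small_ramp_model(2.5)
  edges <- seq(-4, 4, by = 0.2)
  h <- sample_boltzmann_histogram(m, n_steps = 1e8, dt = 0.02, seed = 3,
                                  bin_edges = edges, z0 = 0)
  p <- h$counts / sum(h$counts)
  bulk <- abs(h$mids) < 0.8
  vapor <- abs(h$mids) > 2
  ratio <- mean(p[vapor]) / mean(p[bulk])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("3-D Brownian fixture has exact increment statistics", {
  tr <- simulate_brownian3d(0, n_steps = 100, dt = 1, seed = 1)
  expect_true(all(tr$samples == 0))
  a <- simulate_brownian3d(2e-3, n_steps = 1000, dt = 1, seed = 9)
  b <- simulate_brownian3d(2e-3, n_steps = 1000, dt = 1, seed = 9)
  expect_identical(a$samples, b$samples)
  big <- simulate_brownian3d(1e-3, n_steps = 1e6, dt = 1, seed = 2)
  incr <- diff(big$samples)
  expect_equal(var(as.vector(incr)), 2e-3, tolerance = 0.02)
  expect_error(simulate_brownian3d(-1, 10, 1, 1), "non-negative")
})
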