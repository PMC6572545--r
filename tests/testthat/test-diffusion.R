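test_that("autocovariance has exact small-case values", {
  ## alternating sequence: C(0) = a^2, C(1) = -a^2 under the unbiased
  ## normalization (mean is exactly zero for even length)
  a <- 0.7
  x <- rep(c(a, -a), 500)
  ac <- autocovariance(x, max_lag = 4, dt = 1)
  expect_equal(ac$C[1], a^2)
  expect_equal(ac$C[2], -a^2)
  ## C(0) equals the denominator-n sample variance to machine precision
  set.seed(6)
  y <- rnorm(1234)
  acy <- autocovariance(y, max_lag = 10, dt = 0.5)
  expect_equal(acy$C[1], mean((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(acy$lags, (0:10) * 0.5)
  expect_error(autocovariance(rep(1, 100)), "constant trajectory")
})

test_that("white noise decorrelates at all positive lags", {
  set.seed(7)
  x <- rnorm(1e5)
  ac <- autocovariance(x, max_lag = 10, dt = 1)
  expect_true(all(abs(ac$C[-1]) < 3 / sqrt(1e5) * ac$C[1]))
})

test_that("OU autocovariance decays with the analytic correlation time", {
  m <- flat_model(1e-3)
  k <- 2000
  tr <- simulate_langevin(m, bias_spec(0, k), n_steps = 4e6, dt = 1e-3,
                          seed = 21)
  ac <- autocovariance(tr, max_lag = 4000)
  tau_true <- kBT(300) / (k * 1e-3)  # 1.25 ps
  sel <- ac$C > 0.2 * ac$C[1]
  fit <- lm(log(ac$C[sel]) ~ ac$lags[sel])
  expect_equal(-1 / coef(fit)[[2]], tau_true, tolerance = 0.1)
})

test_that("correlation integral matches closed forms and contracts", {
  tau <- 2
  t_ <- seq(0, 40, by = 0.01)
  C <- 3 * exp(-t_ / tau)
  ac <- structure(list(lags = t_, C = C, dt = 0.01, n = length(t_)),
                  class = "autocovariance")
  ## decays through the 1% threshold; analytic integral = c0 * tau
  expect_equal(correlation_integral(ac), 3 * tau, tolerance = 0.015)
  expect_equal(correlation_integral(ac, method = "exp-tail"), 3 * tau,
               tolerance = 0.01)
  ## linearity
  ac2 <- ac; ac2$C <- 5 * ac$C
  expect_equal(correlation_integral(ac2), 5 * correlation_integral(ac))
  ## truncation: data beyond the first sign change is ignored
  Cc <- 1 - t_  # crosses zero at t = 1
  aca <- structure(list(lags = t_, C = Cc, dt = 0.01, n = 10),
                   class = "autocovariance")
  acb <- aca; acb$C[t_ > 1.5] <- 100
  expect_equal(correlation_integral(aca, tail_threshold = 0),
               correlation_integral(acb, tail_threshold = 0))
  ## no crossing and no decay: full-range fallback with warning
  flat_ac <- structure(list(lags = 0:10, C = rep(1, 11), dt = 1, n = 10),
                       class = "autocovariance")
  expect_warning(correlation_integral(flat_ac), "no zero crossing")
})

test_that("the window estimator recovers D exactly for OU dynamics", {
  ## var^2 / int C = D identity; k = 2000 kJ/mol/nm^2, D = 1e-3 nm^2/ps
  m <- flat_model(1e-3)
  est <- vapply(1:3, function(i)
    diffusion_from_window(simulate_langevin(m, bias_spec(0, 2000),
                                            n_steps = 4e6, dt = 1e-3,
                                            seed = i))$D, 0)
  expect_equal(mean(est), 1e-3, tolerance = 0.1)
  ## bias-strength invariance: halved force constant, same D
  ## halved k doubles the correlation time, so allow a longer lag window
  est2 <- vapply(1:3, function(i)
    diffusion_from_window(simulate_langevin(m, bias_spec(0, 1000),
                                            n_steps = 4e6, dt = 1e-3,
                                            seed = 10 + i),
                          max_lag = 20000)$D, 0)
  expect_equal(mean(est2), mean(est), tolerance = 0.1)
})

test_that("rescaling the time axis rescales D inversely", {
  m <- flat_model(1e-3)
  tr <- simulate_langevin(m, bias_spec(0, 2000), n_steps = 4e5, dt = 0.01,
                          seed = 31, thin = 5)
  d1 <- diffusion_from_window(tr)$D
  tr2 <- tr
  tr2$dt <- tr$dt * 3
  expect_equal(diffusion_from_window(tr2)$D, d1 / 3, tolerance = 1e-10)
})

test_that("the diffusion profile resolves a factor-2 vapor/bulk ramp", {
  m <- ramp_model(d_bulk = 1e-3, factor = 2)
  trajs <- list()
  for (cen in c(0, 5.9)) {
    for (r in 1:5) {
      trajs[[length(trajs) + 1]] <- simulate_langevin(
        m, bias_spec(cen, 2000), n_steps = 4e5, dt = 0.01,
        seed = slabperm:::derive_seed(77, round(cen * 10), r), thin = 10)
    }
  }
  dp <- diffusion_profile(trajs)
  expect_equal(dp$z, sort(dp$z))
  expect_equal(dp$n, c(5, 5))
  expect_equal(dp$D[2] / dp$D[1], 2, tolerance = 0.15)
  expect_equal(dp$D_m2s, dp$D * 1e-6)
})

test_that("MSD diffusion matches the Brownian ground truth and scales", {
  tr0 <- simulate_brownian3d(1e-3, n_steps = 1000, dt = 1, seed = 1)
  still <- tr0
  still$samples <- still$samples * 0
  expect_equal(msd_diffusion(still)$D, 0)
  doubled <- tr0
  doubled$samples <- 2 * tr0$samples
  expect_equal(msd_diffusion(doubled)$D, 4 * msd_diffusion(tr0)$D)
  est <- vapply(1:5, function(i)
    msd_diffusion(simulate_brownian3d(1e-3, n_steps = 2e5, dt = 1,
                                      seed = 40 + i))$D, 0)
  expect_equal(mean(est), 1e-3, tolerance = 0.1)
  expect_error(msd_diffusion(tr0, fit_window = c(0.1, 0.11)), "10 lags")
})

test_that("restrained-ACF and free-MSD estimators agree on constant D", {
  m <- flat_model(1e-3)
  acf_est <- mean(vapply(1:4, function(i)
    diffusion_from_window(simulate_langevin(m, bias_spec(0, 2000),
                                            n_steps = 4e5, dt = 0.01,
                                            seed = 50 + i, thin = 5))$D, 0))
  msd_est <- mean(vapply(1:4, function(i)
    msd_diffusion(simulate_brownian3d(1e-3, n_steps = 5e5, dt = 1,
                                      seed = 60 + i))$D, 0))
  expect_equal(acf_est, msd_est, tolerance = 0.1)
})
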