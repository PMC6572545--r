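test_that("window histograms conserve retained samples", {
  tr <- fake_window(seq(0.005, 0.995, length.out = 100))
  edges <- seq(0, 1, by = 0.1)
  h <- histogram_windows(tr, edges, discard_fraction = 0)[[1]]
  expect_equal(sum(h$counts), 100)
  expect_equal(h$n_samples, 100)
  h2 <- histogram_windows(tr, edges, discard_fraction = 0.5)[[1]]
  expect_equal(sum(h2$counts), 50)
  ## all samples in one bin
  h3 <- histogram_windows(fake_window(rep(0.55, 30)), edges, 0)[[1]]
  expect_equal(sum(h3$counts > 0), 1)
  expect_equal(max(h3$counts), 30)
  ## bins are [left, right) with the last bin closed
  h4 <- histogram_windows(fake_window(c(0, 0.1, 1.0)), edges, 0)[[1]]
  expect_equal(h4$counts[1], 1)
  expect_equal(h4$counts[2], 1)
  expect_equal(h4$counts[10], 1)
  expect_error(histogram_windows(fake_window(c(5, 6)), edges, 0),
               "outside the binning range")
})

test_that("WHAM with one unbiased window is Boltzmann inversion", {
  set.seed(1)
  tr <- fake_window(rnorm(20000, 0.5, 0.2))
  edges <- seq(0, 1, by = 0.05)
  h <- histogram_windows(tr, edges, 0)
  pr <- wham(h)
  counts <- h[[1]]$counts
  keep <- counts > 0
  w_direct <- -kBT(300) * log(counts[keep])
  expect_equal(pr$w - mean(pr$w), w_direct - mean(w_direct),
               tolerance = 1e-10)
})

test_that("overlapping stiff windows on a flat landscape recover w = 0", {
  set.seed(2)
  trs <- lapply(c(0, 0.05), ou_iid_window, n = 1e5)
  edges <- seq(-0.15, 0.2, by = 0.01)
  pr <- wham(histogram_windows(trs, edges, 0))
  ## overlap region between the two centres
  sel <- pr$z >= -0.05 & pr$z <= 0.1
  w <- pr$w[sel] - mean(pr$w[sel])
  expect_lt(sqrt(mean(w^2)), 0.2)
})

test_that("WHAM is gauge-invariant and permutation-invariant", {
  set.seed(3)
  trs <- lapply(seq(0, 0.3, by = 0.05), ou_iid_window, n = 2e4)
  edges <- seq(-0.15, 0.45, by = 0.01)
  h <- histogram_windows(trs, edges, 0)
  a <- wham(h)
  b <- wham(h, bias_offsets = 7.3)  # common shift of all bias energies
  ctr <- function(p) p$w - mean(p$w)
  expect_equal(ctr(a), ctr(b), tolerance = 1e-8)
  d <- wham(h[c(4, 1, 6, 2, 7, 3, 5)])
  expect_equal(ctr(a), ctr(d), tolerance = 1e-10)
  ## non-convergence is an error that reports the residual
  expect_error(wham(h, tol = 0, max_iter = 5), "did not converge")
})

test_that("reference anchoring shifts profiles as declared", {
  pr <- slabperm:::new_fe_profile(z = seq(0, 1, by = 0.1),
                                  w = rep(4.2, 11), temperature = 300)
  r <- set_reference(pr, c(0, 1))
  expect_equal(r$w, rep(0, 11))
  expect_equal(r$reference, "vapor-plateau")
  ## idempotent
  expect_equal(set_reference(r, c(0, 1))$w, r$w)
  ## single-bin region pins that bin to exactly zero
  pr2 <- slabperm:::new_fe_profile(z = c(0, 0.5, 1), w = c(1, 2, 5),
                                   temperature = 300)
  r2 <- set_reference(pr2, c(0.49, 0.51))
  expect_equal(r2$w[2], 0)
  expect_error(set_reference(pr2, c(10, 11)), "overlap")
})

test_that("replicate averaging has exact small-sample arithmetic", {
  mk <- function(w) slabperm:::new_fe_profile(z = c(0, 1), w = w,
                                              temperature = 300)
  same <- average_profiles(replicate(25, mk(c(1, 2)), simplify = FALSE))
  expect_equal(same$w, c(1, 2))
  expect_equal(same$stderr, c(0, 0))
  two <- average_profiles(list(mk(c(0, 0)), mk(c(2, 2))))
  expect_equal(two$w, c(1, 1))
  expect_equal(two$stderr, c(1, 1))  # sd(c(0,2))/sqrt(2) = 1
  expect_error(average_profiles(list(mk(c(1, 2)),
                                     slabperm:::new_fe_profile(
                                       z = c(0, 2), w = c(1, 2),
                                       temperature = 300))),
               "identical grid")
})

test_that("replicate scatter shrinks as 1/sqrt(n)", {
  set.seed(4)
  mk <- function() slabperm:::new_fe_profile(z = 1:5, w = rnorm(5),
                                             temperature = 300)
  se_of <- function(n) mean(average_profiles(
    replicate(n, mk(), simplify = FALSE))$stderr)
  se5 <- mean(replicate(40, se_of(5)))
  se20 <- mean(replicate(40, se_of(20)))
  expect_equal(se5 / se20, 2, tolerance = 0.15)
})

test_that("average free energy over regions is the plain bin mean", {
  pr <- slabperm:::new_fe_profile(z = seq(0, 1, by = 0.25),
                                  w = c(0, 0, 10, 10, 10),
                                  temperature = 300)
  expect_equal(average_free_energy(pr, c(0, 1)), 6)
  expect_equal(average_free_energy(pr, c(0, 0.3)), 0)
  lin <- slabperm:::new_fe_profile(z = seq(-1, 1, by = 0.25),
                                   w = seq(-1, 1, by = 0.25) * 3 + 2,
                                   temperature = 300)
  expect_equal(average_free_energy(lin, c(-1, 1)), 2)  # midpoint value
  expect_error(average_free_energy(pr, c(5, 6)), "no profile bins")
})

test_that("symmetrization averages mirror bins and is idempotent", {
  pr <- slabperm:::new_fe_profile(z = c(-1, 0, 1), w = c(1, 5, 3),
                                  temperature = 300)
  s <- symmetrize(pr)
  expect_equal(s$w, c(2, 5, 2))
  expect_equal(symmetrize(s)$w, s$w)
  asym <- slabperm:::new_fe_profile(z = c(-1, 0, 2), w = c(1, 5, 3),
                                    temperature = 300)
  expect_error(symmetrize(asym), "not symmetric")
})

test_that("mirroring a one-sided profile doubles it about z = 0", {
  pr <- slabperm:::new_fe_profile(z = c(0, 0.5, 1), w = c(4, 2, 0),
                                  temperature = 300)
  m <- mirror_profile(pr)
  expect_equal(m$z, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(m$w, c(0, 2, 4, 2, 0))
  expect_equal(symmetrize(m)$w, m$w)
})

test_that("trajectory-level bootstrap is self-consistent and seeded", {
  set.seed(5)
  trs <- c(lapply(rep(0, 4), ou_iid_window, n = 5000),
           lapply(rep(0.05, 4), ou_iid_window, n = 5000))
  edges <- seq(-0.12, 0.17, by = 0.01)
  b1 <- bootstrap_error(trs, edges, n_boot = 30, seed = 9,
                        discard_fraction = 0)
  expect_true(all(b1$stderr >= 0))
  expect_equal(b1$details$n_boot_failed, 0)
  ## bootstrap mean within 2 stderr of the point estimate wherever the
  ## band is nonzero
  ok <- b1$stderr > 0
  expect_true(all(abs(b1$details$boot_mean[ok] - b1$w[ok]) <=
                    2 * b1$stderr[ok]))
  b2 <- bootstrap_error(trs, edges, n_boot = 30, seed = 9,
                        discard_fraction = 0)
  expect_identical(b1$stderr, b2$stderr)
  b3 <- bootstrap_error(trs, edges, n_boot = 30, seed = 10,
                        discard_fraction = 0)
  expect_false(identical(b1$stderr, b3$stderr))
})
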