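make_fep <- function(z, w, temperature = 300)
  slabperm:::new_fe_profile(z = z, w = w, temperature = temperature)

make_dprof <- function(z, D)
  structure(list(z = z, D = D, D_m2s = D * 1e-6, stderr = rep(0, length(z)),
                 n = rep(1, length(z)), method = "acf"),
            class = "diffusion_profile")

test_that("resistance integrand has closed-form values", {
  z <- seq(-4, 4, by = 0.05)
  fep0 <- make_fep(z, rep(0, length(z)))
  dp <- make_dprof(z, rep(5e-3, length(z)))
  r <- resistance_integrand(fep0, dp, seq(-3, 3, by = 0.1))
  expect_equal(r$r, rep(1 / 5e-3, length(r$z)))
  ## w = kBT ln 2 doubles the local resistance
  fep2 <- make_fep(z, rep(kBT(300) * log(2), length(z)))
  r2 <- resistance_integrand(fep2, dp, seq(-3, 3, by = 0.1))
  expect_equal(r2$r, 2 * r$r)
  ## an 11.79 kJ/mol plateau at 300 K costs the Boltzmann factor
  fepb <- make_fep(z, rep(11.79, length(z)))
  rb <- resistance_integrand(fepb, dp, 0)
  expect_equal(rb$r, exp(11.79 / kBT(300)) / 5e-3, tolerance = 1e-10)
  expect_error(resistance_integrand(fep0, dp, seq(-5, 5, by = 0.1)),
               "beyond the free-energy profile")
  expect_error(resistance_integrand(fep0, make_dprof(z, rep(-1, length(z))),
                                    0), "non-positive")
})

test_that("flat profiles give Pm = D/L to 0.1%", {
  z <- seq(-4, 4, by = 0.05)
  fep <- make_fep(z, rep(0, length(z)))
  dp <- make_dprof(z, rep(5e-3, length(z)))
  pm <- permeability(fep, dp, -2, 2, range_mode = "single")
  ## d0 = 5e-3 nm^2/ps over L = 4 nm: Pm = 1.25e-3 nm/ps = 1.25 m/s
  expect_equal(pm$Pm, 1.25, tolerance = 1e-3)
  expect_equal(pm$Pm_nm_ps, 1.25e-3, tolerance = 1e-3)
  expect_equal(pm$Pm * pm$resistance, 1, tolerance = 1e-12)
  expect_error(permeability(fep, dp, 2, -2), "z1 must be")
  expect_error(permeability(fep, dp, -2, 2, dz = 1), "fewer than 10")
})

test_that("square barrier matches the piecewise closed form to 0.1%", {
  dG <- 6; d0 <- 2e-3; L <- 4; ell <- 1
  z <- seq(-3, 3, by = 0.001)
  w <- ifelse(abs(z) <= ell / 2, dG, 0)
  fep <- make_fep(z, w)
  dp <- make_dprof(z, rep(d0, length(z)))
  pm <- permeability(fep, dp, -2, 2, dz = 0.001)
  pm_exact <- d0 / ((L - ell) + ell * exp(dG / kBT(300))) * 1e3
  expect_equal(pm$Pm, pm_exact, tolerance = 1e-3)
  ## and against the segment oracle
  seg <- data.frame(length = c(1.5, 1, 1.5), w = c(0, dG, 0), D = d0)
  expect_equal(pm$Pm, analytic_permeability(seg, 300), tolerance = 1e-3)
})

test_that("resistances add exactly when an interval is split", {
  z <- seq(-4, 4, by = 0.01)
  set.seed(8)
  wz <- 3 * sin(z) + z^2 / 8
  fep <- make_fep(z, wz)
  dp <- make_dprof(z, 2e-3 + 1e-3 * cos(z / 2))
  whole <- permeability(fep, dp, -3, 3, dz = 0.01)
  left <- permeability(fep, dp, -3, 0.5, dz = 0.01)
  right <- permeability(fep, dp, 0.5, 3, dz = 0.01)
  expect_equal(1 / whole$Pm, 1 / left$Pm + 1 / right$Pm,
               tolerance = 1e-12)
  ## interface mode sums the two mirrored interval resistances
  iface <- permeability(fep, dp, 1.5, 3, range_mode = "interface")
  a <- permeability(fep, dp, -3, -1.5)
  b <- permeability(fep, dp, 1.5, 3)
  expect_equal(1 / iface$Pm, 1 / a$Pm + 1 / b$Pm, tolerance = 1e-12)
})

test_that("raising w lowers Pm; scaling D scales Pm exactly", {
  z <- seq(-4, 4, by = 0.02)
  fep <- make_fep(z, sin(z))
  dp <- make_dprof(z, rep(2e-3, length(z)))
  base <- permeability(fep, dp, -3, 3)
  bump <- make_fep(z, sin(z) + ifelse(abs(z - 1) < 0.5, 2, 0))
  expect_lt(permeability(bump, dp, -3, 3)$Pm, base$Pm)
  dp3 <- make_dprof(z, rep(6e-3, length(z)))
  expect_equal(permeability(fep, dp3, -3, 3)$Pm, 3 * base$Pm,
               tolerance = 1e-12)
})

test_that("the segment oracle has exact trivial values", {
  expect_equal(analytic_permeability(
    data.frame(length = 4, w = 0, D = 5e-3), 300), 1.25)
  seg <- data.frame(length = c(2, 2), w = c(0, kBT(300) * log(3)), D = 1e-3)
  expect_equal(analytic_permeability(seg, 300), 1e-3 / (2 * (1 + 3)) * 1e3)
  expect_error(analytic_permeability(
    data.frame(length = 0, w = 0, D = 1), 300), "zero-length")
})

test_that("selectivity tables have the reported ratio arithmetic", {
  rep_ <- reported_permeabilities()
  full_be <- with(subset(rep_, system == "choline-benzoate" &
                           range == "full"), setNames(Pm, solute))
  tab <- selectivity(full_be)
  expect_equal(signif(selectivity_ratio(tab, "CO2", "CH4"), 3), 2.71e4)
  expect_equal(signif(selectivity_ratio(tab, "H2S", "CO2"), 3), 5.87)
  ## invariants
  expect_equal(selectivity_ratio(tab, "CH4", "CH4"), 1)
  expect_equal(selectivity_ratio(tab, "CO2", "H2S") *
                 selectivity_ratio(tab, "H2S", "CO2"), 1)
  ## ratio invariance under common rescaling
  tab2 <- selectivity(full_be * 13.7)
  expect_equal(tab2$ratio, tab$ratio)
  expect_error(selectivity(c(1, 2)), "named")
})

test_that("interface-range CH4 selectivities reproduce within input rounding", {
  ## the reported interface-range CO2/CH4 and H2S/CH4 selectivities were
  ## evidently computed before the permeabilities were rounded to table
  ## precision; the CH4 entries carry only 2 significant figures
  ## (half-ULP ~3%), so ratios of the rounded values agree to ~5%
  rep_ <- reported_permeabilities()
  for (sys in c("choline-benzoate", "choline-lactate")) {
    P <- with(subset(rep_, system == sys & range == "interface"),
              setNames(Pm, solute))
    tab <- selectivity(P)
    expected <- if (sys == "choline-benzoate") c(7.31e2, 7.75e2, 1.06)
                else c(1.62e2, 1.89e2, 1.17)
    got <- c(selectivity_ratio(tab, "CO2", "CH4"),
             selectivity_ratio(tab, "H2S", "CH4"),
             selectivity_ratio(tab, "H2S", "CO2"))
    expect_equal(got, expected, tolerance = 0.05)
  }
})

test_that("mixing range modes or temperatures is rejected", {
  z <- seq(-4, 4, by = 0.02)
  fep <- make_fep(z, rep(0, length(z)))
  dp <- make_dprof(z, rep(1e-3, length(z)))
  a <- permeability(fep, dp, -2, 2, range_mode = "single")
  b <- permeability(fep, dp, 1, 2, range_mode = "interface")
  expect_error(selectivity(list(x = a, y = b)), "range modes")
})
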