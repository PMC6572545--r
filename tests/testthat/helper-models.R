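# Shared synthetic fixtures, all built in code.

slab_geom <- list(z_int = 2, interface_width = 0.25, slab_half_width = 2)
slab_dens <- list(rho_bulk = 1100, interface_width = 0.3)

# flat free energy, constant diffusion: the OU oracle landscape
flat_model <- function(d0 = 1e-3) {
  build_slab_model(
    pmf_params = c(list(well_depth = 0, plateau = 0), slab_geom),
    diff_params = list(d_vapor = d0, d_bulk = d0, transition_width = 0.25),
    density_params = slab_dens, temperature = 300, box_half_length = 7)
}

# flat free energy with a D(z) ramp (vapor = 2x bulk)
ramp_model <- function(d_bulk = 1e-3, factor = 2) {
  build_slab_model(
    pmf_params = c(list(well_depth = 0, plateau = 0), slab_geom),
    diff_params = list(d_vapor = factor * d_bulk, d_bulk = d_bulk,
                       transition_width = 0.25),
    density_params = slab_dens, temperature = 300, box_half_length = 7)
}

# moderate double-well slab: interior plateau low enough that an unbiased
# brute-force run visits it many times
dw_model <- function() {
  build_slab_model(
    pmf_params = c(list(well_depth = -2, plateau = 3), slab_geom),
    diff_params = list(d_vapor = 2.5e-3, d_bulk = 1e-3,
                       transition_width = 0.25),
    density_params = slab_dens, temperature = 300, box_half_length = 7,
    label = "dw")
}

# compact double-well slab (1 nm half-width, 4 nm half-box): interior
# <-> vapor exchange is ~5x faster than on the full geometry, so
# equilibrium-fidelity checks reach tight statistics at desk scale
small_dw_model <- function() {
  build_slab_model(
    pmf_params = list(well_depth = -2, plateau = 3, z_int = 1,
                      interface_width = 0.2, slab_half_width = 1),
    diff_params = list(d_vapor = 2.5e-3, d_bulk = 1e-3,
                       transition_width = 0.2),
    density_params = slab_dens, temperature = 300, box_half_length = 4,
    label = "small_dw")
}

# compact flat-w slab with a D(z) ramp, for uniform-sampling checks
small_ramp_model <- function(factor = 2.5) {
  build_slab_model(
    pmf_params = list(well_depth = 0, plateau = 0, z_int = 1,
                      interface_width = 0.2, slab_half_width = 1),
    diff_params = list(d_vapor = factor * 1e-3, d_bulk = 1e-3,
                       transition_width = 0.2),
    density_params = slab_dens, temperature = 300, box_half_length = 4)
}

# window_trajectory carrying externally supplied samples (for estimator
# unit tests that need exactly known inputs)
fake_window <- function(samples, dt = 0.1, center = 0, k = 0,
                        temperature = 300) {
  structure(list(samples = samples, dt = dt,
                 bias = bias_spec(center, k), seed = 0,
                 model_id = "fake", temperature = temperature),
            class = "window_trajectory")
}

# i.i.d. equilibrium samples of a harmonic window on a flat landscape
ou_iid_window <- function(center, n, k = 2000, temperature = 300) {
  fake_window(rnorm(n, center, sqrt(kBT(temperature) / k)),
              center = center, k = k, temperature = temperature)
}

default_bins <- function(lo = -0.155, hi = 6.055, bw = 0.01) {
  seq(lo, hi, by = bw)
}
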