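Package: slabperm
Title: Gas Permeability Across Liquid Slabs from Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs solute permeability coefficients across a
    liquid slab with liquid-vapor interfaces from one-dimensional
    umbrella-sampling trajectories. Provides a seeded overdamped
    Langevin generator with position-dependent diffusion as a
    ground-truth-known stand-in for molecular dynamics, the weighted
    histogram analysis method (WHAM) with trajectory-level bootstrap
    errors for the free-energy profile w(z), the positional
    autocovariance estimator for the local diffusion coefficient D(z)
    together with mean-square-displacement bulk diffusion, and the
    inhomogeneous solubility-diffusion integral 1/Pm =
    int exp(w(z)/kBT)/D(z) dz with permselectivity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
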