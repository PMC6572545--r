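# slabperm

Estimation of gas permeability coefficients across liquid slabs with
liquid–vapor interfaces — for example small gas molecules (CO2, H2S,
CH4) crossing an ionic-liquid film — from one-dimensional
umbrella-sampling trajectories.

The core quantity is the inhomogeneous solubility–diffusion
permeability

    1/Pm = ∫_{z1}^{z2} exp(w(z)/kBT) / D(z) dz ,

where `w(z)` is the potential of mean force of the solute along the
slab normal (zero in the vapor phase) and `D(z)` its local diffusion
coefficient. The package provides the full chain that turns biased
trajectories into `Pm` and permselectivities `P_a/P_b`:

* **Synthetic umbrella-sampling generator** — overdamped Langevin
  dynamics (Metropolis-adjusted Euler–Maruyama, position-dependent `D`
  with the gradient-of-D drift, reflecting box) on parametric slab
  models with closed-form `w`, `D` and density, so every estimator can
  be validated against known ground truth. Default protocol: 6 windows
  1 nm apart staggered over 10 offsets (60 centres at 0.1 nm),
  k = 2000 kJ/mol/nm², 4 ns per window, 25 replicate ladders, 300 K.
* **WHAM** — self-consistent reconstruction of `w(z)` from window
  histograms (bin-averaged harmonic bias factors, 0.01 nm bins,
  tol 1e-7 kJ/mol), vapor-plateau referencing, replicate averaging,
  and trajectory-level bootstrap error bands.
* **Diffusion profiles** — the positional-autocovariance estimator
  `D(z_i) = var(z)² / ∫ C_z(t) dt` per restrained window (exact for an
  Ornstein–Uhlenbeck window), averaged across replicates; plus
  all-origin MSD bulk diffusion via the Einstein relation.
* **Permeability & selectivity** — trapezoidal evaluation of the
  resistance integral over full or interfacial (`|z| ∈ [z1, z2]`, both
  sides summed) ranges, a piecewise-constant closed-form oracle, and
  ordered-ratio selectivity tables reported to 3 significant figures.
* **I/O & pipeline** — xvg-style two-column time series with TSV
  sidecars, TSV profiles with YAML headers, a validated YAML config,
  and `run_pipeline()` driving simulate → WHAM → diffusion →
  permeability → selectivity, fully reproducible from one seed.

## Worked example

```r
library(slabperm)

models <- example_slab_models()      # methane-like and acid-gas-like solutes
m <- models$methane_like
evaluate_model(m, c(0, 2, 7))[, c("z", "w", "D")]
#>   z            w     D
#> 1 0 1.179000e+01 0.002      # +11.79 kJ/mol interior plateau, bulk D
#> 2 2 3.898955e+00 0.0035     # interfacial well region
#> 3 7 2.431731e-08 0.005      # vapor reference: w = 0, fast D

## one restrained window: OU statistics and the Eq.-2 identity
tr <- simulate_langevin(m, bias_spec(5.9, 2000), n_steps = 4e5,
                        dt = 0.01, seed = 1, thin = 10)
var(tr$samples)                  # 0.0012345: kBT/k = 2.494/2000 nm^2
diffusion_from_window(tr)$D      # 0.0051989: vapor-side truth is 0.005
```

The full two-solute study lives in `analysis/` as numbered stages over
a shared `analysis/config.yaml`:

```sh
Rscript analysis/01_simulate.R      # campaigns + sampling diagnostics
Rscript analysis/02_wham.R          # w(z) with bootstrap bands -> results/fep_*.tsv
Rscript analysis/03_diffusion.R     # D(z) + MSD cross-check    -> results/dprof_*.tsv
Rscript analysis/04_permeability.R  # Pm per range              -> results/permeability.tsv
Rscript analysis/05_selectivity.R   # selectivity tables        -> results/selectivity.tsv
```

Stage-4 output (synthetic solutes, against the exact integral on the
ground-truth profiles):

```
methane_like   full      Pm =   0.006704 m/s (analytic   0.006222,  +7.8%)
methane_like   interface Pm =      0.109 m/s (analytic    0.09972,  +9.3%)
acid_gas_like  full      Pm =      1.605 m/s (analytic      1.682,  -4.5%)
acid_gas_like  interface Pm =      2.109 m/s (analytic      2.162,  -2.5%)
```

The methane-like solute's resistance is dominated by its unfavourable
interior plateau (`exp(11.79/2.494) ≈ 113` per unit length), so its
full-slab permeability sits more than two orders of magnitude below the
acid-gas solute's, and its interfacial-range permeability is ~16x its
full-slab value — the same mechanism that makes choline ionic liquids
dramatically CH4-rejecting. Stage 5 also runs the selectivity
arithmetic on the literature-reported permeability coefficients shipped
in `inst/extdata/reported_permeabilities.tsv`, reproducing the reported
CO2/CH4 (> 1e4), H2S/CH4 (> 1e5) and H2S/CO2 (~6) full-range ratios.

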