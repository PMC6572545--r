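---
title: "Permeability of gas solutes across liquid slabs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permeability of gas solutes across liquid slabs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gas molecule crossing a liquid slab with two liquid–vapor interfaces
(for example CO2, H2S or CH4 entering an ionic-liquid film) experiences a
position-dependent free energy $w(z)$ and a position-dependent diffusion
coefficient $D(z)$ along the slab normal $z$. In the inhomogeneous
solubility–diffusion model the steady-state permeability coefficient
$P_m$ is

$$\frac{1}{P_m} \;=\; \int_{z_1}^{z_2} \frac{e^{\,w(z)/k_BT}}{D(z)}\,dz ,$$

a series sum of local resistances $e^{w/k_BT}/D$: regions where the
solute is both unwelcome (large $w$) and slow (small $D$) dominate.
Permselectivity between two solutes is the ratio of their $P_m$.

`slabperm` implements the full estimation chain for this quantity from
one-dimensional umbrella-sampling (US) trajectories:

1. a **synthetic trajectory generator** with exactly known ground truth
   (`build_slab_model()`, `simulate_langevin()`,
   `generate_us_campaign()`),
2. **WHAM** reconstruction of $w(z)$ from biased window histograms with
   replicate averaging and trajectory-level bootstrap errors
   (`wham()`, `average_profiles()`, `bootstrap_error()`),
3. the **positional-autocovariance estimator** of $D(z)$ from restrained
   windows and the Einstein/MSD estimator of bulk diffusion
   (`diffusion_from_window()`, `msd_diffusion()`),
4. the **permeability integral** and **selectivity tables**
   (`permeability()`, `selectivity()`).

Because no reference trajectory data are distributable, the generator is
a first-class, tested component: every downstream estimator is validated
against landscapes whose $w$, $D$ and density are known in closed form.

## The synthetic slab model

A `slab_model` defines an even free-energy profile built from a smoothed
interior plateau (a normalized product of logistic sigmoids of width
`interface_width` centred at `±slab_half_width`) plus Gaussian wells of
the same width at the interfaces `±z_int`; a sigmoid blend between
`d_vapor` and `d_bulk` for $D(z)$; and a tanh profile for the mass
density. All derivatives are analytic. The construction guarantees
$w(0) = \text{plateau}$ and $w(\pm\text{box edge}) = 0$ (the vapor
reference) to within $10^{-6}$ kJ/mol for the default geometry.

The default geometry mirrors the reference systems: interfaces at
$|z| = 2$ nm, a 14 nm box ($z \in [-7, 7]$ nm), 300 K. The example
models (`example_slab_models()`) use an interior plateau of
+11.79 kJ/mol for the methane-like solute and −7.84 kJ/mol for the
acid-gas-like solute — the scale of the reported interior free-energy
averages — and bulk diffusivities of order $10^{-9}$ m²/s
($10^{-3}$ nm²/ps) rising by a factor 2.5 towards the low-density
interface, where diffusion is fastest.

### What the generator emulates, and what it does not

The generator produces overdamped Langevin dynamics of the reaction
coordinate only. It reproduces the statistical structure that the
estimators consume: Boltzmann-distributed biased windows, realistic
within-window autocorrelation times $\tau = k_BT/(kD)$, replicate
scatter, and a density-correlated $D(z)$. It does **not** emulate
atomistic detail: no molecular force field, no solvent memory
(friction is Markovian), no coupling between $z$ and the transverse
degrees of freedom. Passing tests therefore demonstrate correctness of
the estimators and pipeline, not the accuracy of any particular
molecular model.

### Integrator

The update rule is the Euler–Maruyama (EM) discretization of overdamped
dynamics with position-dependent diffusion, including the
gradient-of-$D$ (spurious drift) term:

$$z' = z + \Big[\tfrac{D(z)}{k_BT}\,F(z) + D'(z)\Big]\,dt
       + \sqrt{2D(z)\,dt}\;\xi,$$

with $F = -(w' + u')$ and reflecting walls at the box edges. The
$D'(z)$ term is essential: without it the stationary law would be
$\propto 1/D(z)$ instead of Boltzmann, and a regression test checks
that a flat-$w$, ramped-$D$ model samples uniformly.

By default this EM move is used as the *proposal* of a
Metropolis-adjusted (smart Monte Carlo) step: the move to $z'$ is
accepted with probability
$\min\{1, \pi(z')q(z\mid z')/[\pi(z)q(z'\mid z)]\}$, where
$\pi \propto e^{-(w+u)/k_BT}$. This removes the $O(dt)$ bias of the EM
stationary distribution entirely. The choice matters quantitatively: at
the largest stable time step the plain EM window variance is inflated by
$\sim k D\,dt/2k_BT$ (1–2 %), and WHAM stitches these per-window errors
into a systematic ramp of several kJ/mol across a 60-window ladder.
With the Metropolis correction the sampled measure is exact at any
stable $dt$; rejection rates are below 0.2 % at the defaults, so the
short-time dynamics — and hence the autocovariance-based $D$
estimates — are essentially unperturbed (the realized acceptance rate
is recorded on every trajectory). Plain EM remains available via
`metropolis = FALSE`. A stability guard requires
$dt\,k\,D_{\max}/k_BT < 0.1$.

Randomness comes from a compiled xoshiro256++ generator seeded per
trajectory from the master seed and the (window, replicate) indices, so
campaigns are bit-reproducible and never touch R's RNG state.

### Campaign protocol (the study conditions)

The default `generate_us_campaign()` settings encode the reference US
protocol: 6 windows separated by 1.0 nm, staggered over 10 offset runs
of 0.1 nm (60 distinct centres at an effective 0.1 nm spacing), a
harmonic restraint of $k = 2000$ kJ/mol/nm² (the printed
"kJ/mol/nm" is read as kJ/mol/nm², the only dimensionally consistent
unit for a harmonic spring), 4 ns per window, and 25 replicate ladders
whose profiles are averaged. The package integrates 4 ns at
$dt = 0.01$ ps ($4\times10^5$ steps) and stores every 10th position
(sampling interval 0.1 ps, comfortably resolving the window correlation
time of ≈1.25 ps), mimicking an MD engine's output stride.

## WHAM

`wham()` is the standard self-consistent estimator on a shared bin grid:

$$p(b) = \frac{\sum_i n_i(b)}{\sum_i N_i\, e^{(f_i - u_i(b))/k_BT}},
\qquad
f_i = -k_BT \ln \sum_b p(b)\, e^{-u_i(b)/k_BT},$$

iterated until $\max_i |\Delta f_i| < 10^{-7}$ kJ/mol (`tol`), with
$w(z_b) = -k_BT\ln p(b)$ reported on bins with nonzero counts and
empty bins excluded rather than assigned infinite $w$. Two numerical
choices matter with stiff restraints:

* **Bin-averaged bias factors.** The window width
  $\sigma = \sqrt{k_BT/k} \approx 0.035$ nm is comparable to any
  reasonable bin. Evaluating $e^{-u_i/k_BT}$ at the bin centre biases
  the reconstruction; the package instead uses the analytic average of
  the Gaussian bias factor over each bin (via the normal CDF).
* **Bin width 0.01 nm.** Even with averaged bias factors, 0.05 nm bins
  leave a systematic stitching ramp of order 1 kJ/mol across the
  60-window ladder (the within-bin variation of $p$ is large when
  bins exceed half a window width); 0.01 nm bins push this below
  0.1 kJ/mol. The iteration restricts each window to the bins where
  its bias factor is non-negligible, so the finer grid stays cheap.

Windows are referenced to the vapor plateau (`set_reference()`, by
default the outermost 10 % of the sampled range, where $w \equiv 0$ by
construction), replicate profiles are averaged pointwise with the
between-replicate standard error attached, and `bootstrap_error()`
resamples *whole window trajectories* with replacement — sample-level
resampling would understate errors because within-window samples are
autocorrelated with $\tau \approx 1.25$ ps. Replicates that fail to
converge are reported, never silently dropped. The first 10 % of every
window is discarded as equilibration.

On the default campaign over a known double-well slab, the averaged
referenced profile recovers the ground truth within 0.3 kJ/mol RMSE
(typically 0.05–0.25), and agrees with a brute-force Boltzmann
inversion of a single long unbiased run at the same tolerance. The
brute-force oracle is only statistically feasible for a moderate
interior plateau (3 kJ/mol here): the number of interior↔vapor
exchanges, not the step count, limits its accuracy, and a 11.79 kJ/mol
plateau would see essentially none at desk scale.

## Position-dependent diffusion

For a harmonically restrained, equilibrated window the positional
autocovariance $C_z(t)$ yields the local diffusion coefficient

$$D(z_i) = \frac{\mathrm{var}(z)^2}{\int_0^\infty C_z(t)\,dt},
\qquad z_i = \langle z\rangle_i .$$

For an Ornstein–Uhlenbeck window this identity is exact:
$\mathrm{var} = k_BT/k$, $\int C = \mathrm{var}\cdot\tau$ and
$\tau = k_BT/(kD)$. The estimator is invariant to the restraint
strength, and the window position is taken as the sample mean, not the
restraint centre. `autocovariance()` computes $C_z$ by FFT with
unbiased $1/(n-k)$ normalization, so $C(0)$ equals the
(denominator-$n$) sample variance to machine precision.

The integral is truncated at the first zero crossing of $C$ (linearly
interpolated), or earlier once $C$ has decayed below 1 % of $C(0)$ —
the remaining exponential tail contributes ≈1 % while the accumulated
noise of the sample ACF tail (which is strongly correlated across lags
and occasionally fails to cross zero at all) can contribute far more.
An exponential-tail fit is available as an alternative
(`method = "exp-tail"`). Per-centre estimates are averaged over the 25
replicates with standard errors; degenerate windows are excluded with a
warning.

Bulk diffusion uses the all-time-origin MSD of an unbiased 3-D
trajectory (FFT-based) and the Einstein relation $D =$ slope$/6$, fit
over 10–50 % of the maximal lag (default: lags up to $n/10$). The two
estimators agree within a few percent on a constant-$D$ model, and a
20-replica MSD average recovers the ground truth within ~1 %.

## Permeability and selectivity

`permeability()` interpolates $w$ and $D$ linearly onto a uniform grid
(default 0.01 nm), evaluates the integrand in log space (guarding
overflow for large $w$), and integrates by the trapezoidal rule; the
free-energy profile must cover the integration range, while $D$ is
extrapolated as its nearest value beyond the outermost window centre
(with a warning). Resistances of sub-intervals add exactly. The
interfacial mode integrates both mirrored intervals
$[-z_2,-z_1]\cup[z_1,z_2]$ and sums the two resistances, since a full
crossing traverses both interfaces; a single-interval mode is also
provided because the reporting convention for interface-only tables is
not fixed. `analytic_permeability()` provides the exact closed form for
piecewise-constant profiles and serves as the oracle in the tests.
Output units are m/s ($1$ nm/ps $= 10^3$ m/s; $1$ nm²/ps $= 10^{-6}$
m²/s — the unit pair is carried explicitly on diffusion profiles).

`selectivity()` forms all ordered ratios $P_a/P_b$, printed to 3
significant figures. Feeding it the literature-reported permeability
coefficients of CH4, CO2 and H2S across the two choline ionic liquids
(shipped in `inst/extdata/`) reproduces the reported full-range
CO2/CH4, H2S/CH4 and H2S/CO2 selectivities to 3 significant figures.
The interfacial-range CH4 ratios are reported in the source to higher
precision than survives the 2-significant-figure rounding of the CH4
permeabilities; ratios of the rounded values agree within ~3 %, which
the tests check at a 5 % input-rounding tolerance.

## Problem sizes and reproducibility

The shipped analyses and tests run the protocol at its stated size
(60 × 25 windows of 4 ns); the brute-force fidelity oracles use
$0.5$–$2\times10^9$ steps, sized so that region-exchange statistics —
the accuracy-limiting factor — reach a few hundred transitions.
`run_pipeline()` executes the whole chain per solute from a single
validated YAML/JSON config; every artifact records the config hash and
seeds, and reruns are numerically identical. The numbered scripts under
`analysis/` narrate the same chain stage by stage, writing TSV/JSON
artifacts under `results/`, and `scripts/acceptance.R` recomputes the
headline quantities from scratch.

## Known limitations

* The generator's Markovian friction cannot probe memory effects; a
  generalized-Langevin extension (memory kernels) is out of scope.
* WHAM assumes uncorrelated samples when weighting windows by $N_i$;
  autocorrelation-corrected effective sample sizes are not applied
  (errors are instead measured empirically across replicates and by
  trajectory-level bootstrap).
* $D(z)$ is extrapolated as constant beyond the outermost window
  centre; profiles should cover the integration range of interest.
* The positional-autocovariance estimator assumes the window samples a
  locally harmonic, locally constant-$D$ neighbourhood; very soft
  restraints over steep $D(z)$ gradients blur the assigned position.
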