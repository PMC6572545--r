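#' Histogram umbrella windows on a common grid
#'
#' Bins each trajectory's retained samples into half-open bins
#' `[left, right)` (last bin closed). The first `discard_fraction` of each
#' trajectory is dropped as equilibration.
#'
#' @param trajectories List of `window_trajectory`.
#' @param bin_edges Strictly increasing bin edges (nm), shared by all
#'   windows.
#' @param discard_fraction Fraction of initial samples discarded (in
#'   `[0, 1)`; default 0.1).
#' @return List of `window_histogram` objects (fields `bin_edges`,
#'   `counts`, `bias`, `n_samples`, `temperature`).
#' @export
histogram_windows <- function(trajectories, bin_edges,
                              discard_fraction = 0.1) {
  if (inherits(trajectories, "window_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1,
            discard_fraction >= 0, discard_fraction < 1)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "window_trajectory"))
    x <- tr$samples
    n0 <- floor(discard_fraction * length(x))
    if (n0 > 0) x <- x[-seq_len(n0)]
    idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
    inside <- idx >= 1 & idx <= length(bin_edges) - 1
    if (!any(inside))
      stop(sprintf("trajectory (centre %g nm) lies entirely outside the binning range",
                   tr$bias$center))
    counts <- tabulate(idx[inside], nbins = length(bin_edges) - 1)
    structure(list(bin_edges = bin_edges, counts = counts, bias = tr$bias,
                   n_samples = sum(counts), temperature = tr$temperature),
              class = "window_histogram")
  })
}

## Analytic bin average of exp(-u_i(z)/kBT) for a harmonic bias: with
## sd = sqrt(kBT/k),
##   (1/db) int_bin exp(-k (z-c)^2 / 2 kBT) dz
##     = sqrt(2 pi) * sd / db * [Phi((r-c)/sd) - Phi((l-c)/sd)].
## Evaluating at the bin centre instead biases w visibly when the window
## width is comparable to the bin width (stiff restraints).
bias_factor_matrix <- function(bin_edges, biases, kT, offsets = 0) {
  l <- head(bin_edges, -1); r <- bin_edges[-1]
  db <- r - l
  offsets <- rep_len(offsets, length(biases))
  E <- matrix(0, nrow = length(l), ncol = length(biases))
  for (i in seq_along(biases)) {
    b <- biases[[i]]
    if (b$force_constant == 0) {
      E[, i] <- 1
    } else {
      s <- sqrt(kT / b$force_constant)
      E[, i] <- sqrt(2 * pi) * s / db *
        (pnorm((r - b$center) / s) - pnorm((l - b$center) / s))
    }
    if (offsets[i] != 0) E[, i] <- E[, i] * exp(-offsets[i] / kT)
  }
  E
}

new_fe_profile <- function(z, w, stderr = NULL, reference = "raw",
                           temperature, details = NULL) {
  o <- order(z)
  structure(list(z = z[o], w = w[o],
                 stderr = if (!is.null(stderr)) stderr[o],
                 reference = reference, temperature = temperature,
                 details = details),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile: %d bins, z in [%.3g, %.3g] nm, reference '%s', T = %g K>\n",
    length(x$z), min(x$z), max(x$z), x$reference, x$temperature))
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  d <- data.frame(z = x$z, w = x$w)
  if (!is.null(x$stderr)) d$stderr <- x$stderr
  d
}

#' Weighted histogram analysis method
#'
#' Self-consistent WHAM over a set of window histograms sharing a bin grid
#' and temperature: iterates
#' `p(b) = sum_i n_i(b) / sum_i N_i exp((f_i - u_i(b))/kBT)` and
#' `f_i = -kBT log sum_b p(b) exp(-u_i(b)/kBT)` until
#' `max |delta f_i| < tol`, then reports `w(z_b) = -kBT log(p(b)/db)` on
#' bins with nonzero total counts (reference `"raw"`, i.e. an arbitrary
#' additive constant). The harmonic bias Boltzmann factor is averaged
#' analytically over each bin. Histograms with identical bias are pooled.
#'
#' @param histograms List of `window_histogram` (shared grid and
#'   temperature).
#' @param tol Convergence tolerance on `max |delta f_i|` in kJ/mol.
#' @param max_iter Maximum number of iterations; non-convergence is an
#'   error reporting the final residual.
#' @param bias_offsets Optional per-window constants (kJ/mol) added to the
#'   bias energies; the profile is invariant to a common shift (gauge
#'   invariance).
#' @return A `free_energy_profile`; `$details` carries the window free
#'   energies `f`, iteration count and residual history tail.
#' @export
wham <- function(histograms, tol = 1e-7, max_iter = 1e5, bias_offsets = 0) {
  if (inherits(histograms, "window_histogram")) histograms <- list(histograms)
  stopifnot(length(histograms) >= 1)
  edges <- histograms[[1]]$bin_edges
  temp <- histograms[[1]]$temperature
  for (h in histograms) {
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop("histograms must share a common bin grid")
    if (abs(h$temperature - temp) > 1e-9)
      stop("histograms must share a common temperature")
  }
  kT <- kBT(temp)
  ## pool histograms with identical bias (same sampled distribution)
  key <- vapply(histograms, function(h)
    paste(h$bias$center, h$bias$force_constant), "")
  offsets <- rep_len(bias_offsets, length(histograms))
  groups <- split(seq_along(histograms), key)
  biases <- lapply(groups, function(i) histograms[[i[1]]]$bias)
  goff <- vapply(groups, function(i) offsets[i[1]], 0)
  counts <- vapply(groups, function(i)
    Reduce(`+`, lapply(histograms[i], `[[`, "counts")),
    numeric(length(edges) - 1))
  counts <- matrix(counts, ncol = length(groups))
  nb <- rowSums(counts)
  Ni <- colSums(counts)
  if (all(nb == 0)) stop("all bins empty")
  E <- bias_factor_matrix(edges, biases, kT, goff)
  fit <- cpp_wham(nb, Ni, E, kT, tol, as.integer(max_iter))
  if (!fit$converged)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                 as.integer(max_iter), fit$residual))
  tail10 <- fit$residual_tail
  if (length(tail10) >= 2 && any(diff(tail10) > 0))
    warning("WHAM residual was not monotone over the final iterations")
  mids <- (head(edges, -1) + edges[-1]) / 2
  db <- diff(edges)
  keep <- nb > 0
  w <- -kT * log(fit$p[keep] / db[keep])
  new_fe_profile(mids[keep], w, reference = "raw", temperature = temp,
                 details = list(f = fit$f, windows = biases,
                                iterations = fit$iterations,
                                residual = fit$residual,
                                residual_tail = tail10,
                                counts = nb))
}

#' Anchor the reference of a free-energy profile
#'
#' Shifts the profile so its mean over `region` is zero. The conventional
#' choice is a vapor-phase region where the true excess free energy
#' vanishes.
#'
#' @param profile A `free_energy_profile`.
#' @param region Length-2 numeric `c(lo, hi)` in nm.
#' @param tag Reference tag recorded on the result.
#' @return The shifted `free_energy_profile`.
#' @export
set_reference <- function(profile, region, tag = "vapor-plateau") {
  stopifnot(inherits(profile, "free_energy_profile"),
            is.numeric(region), length(region) == 2)
  sel <- profile$z >= min(region) & profile$z <= max(region)
  if (!any(sel)) stop("reference region does not overlap the profile grid")
  profile$w <- profile$w - mean(profile$w[sel])
  profile$reference <- tag
  profile
}

#' Vapor reference region of a profile grid
#'
#' Outermost `fraction` of the grid span, on the upper side (one-sided
#' grids) or both sides (grids spanning the whole slab).
#'
#' @param profile A `free_energy_profile`.
#' @param fraction Fraction of the grid span (default 0.1).
#' @return For `side = "upper"` a length-2 region usable by
#'   [set_reference()]; for `side = "both"` the upper region is returned
#'   and symmetry is assumed to have been applied already.
#' @param side `"upper"` or `"both"`.
#' @export
vapor_region <- function(profile, fraction = 0.1, side = "upper") {
  rng <- range(profile$z)
  span <- diff(rng)
  switch(side,
         upper = c(rng[2] - fraction * span, rng[2]),
         both = c(rng[2] - fraction * span, rng[2]),
         stop("side must be 'upper' or 'both'"))
}

#' Average replicate free-energy profiles
#'
#' Pointwise mean over replicates on an identical grid, with the pointwise
#' standard error across replicates attached.
#'
#' @param profiles List of `free_energy_profile` with identical grids and
#'   reference conventions.
#' @return A `free_energy_profile` with `stderr`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  z <- profiles[[1]]$z
  ref <- profiles[[1]]$reference
  temp <- profiles[[1]]$temperature
  for (p in profiles) {
    if (length(p$z) != length(z) || !isTRUE(all.equal(p$z, z)))
      stop("profiles must share an identical grid")
    if (!identical(p$reference, ref))
      stop("profiles must share a reference convention")
  }
  W <- vapply(profiles, `[[`, numeric(length(z)), "w")
  W <- matrix(W, nrow = length(z))
  n <- ncol(W)
  se <- if (n > 1) apply(W, 1, sd) / sqrt(n) else rep(0, length(z))
  new_fe_profile(z, rowMeans(W), stderr = se, reference = ref,
                 temperature = temp, details = list(n_replicates = n))
}

#' Restrict replicate profiles to their common grid
#'
#' Replicate WHAM profiles can differ in which sparsely-sampled edge bins
#' survive; this helper subsets each to the bins present in all of them so
#' [average_profiles()] applies.
#'
#' @param profiles List of `free_energy_profile`.
#' @return List of profiles on the shared grid.
#' @export
common_grid <- function(profiles) {
  zkeys <- lapply(profiles, function(p) round(p$z, 9))
  shared <- Reduce(intersect, zkeys)
  if (length(shared) == 0) stop("profiles share no grid points")
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    sel <- zkeys[[i]] %in% shared
    new_fe_profile(p$z[sel], p$w[sel],
                   stderr = if (!is.null(p$stderr)) p$stderr[sel],
                   reference = p$reference, temperature = p$temperature,
                   details = p$details)
  })
}

#' Trajectory-level bootstrap errors for a WHAM profile
#'
#' Resamples whole window trajectories with replacement within each bias
#' group (trajectories are internally autocorrelated, so sample-level
#' resampling would understate the error), recomputes WHAM per bootstrap
#' replicate, and attaches the pointwise standard deviation across
#' replicates to the original point estimate (which is unchanged).
#'
#' @param trajectories List of `window_trajectory` (e.g. one campaign
#'   replicate).
#' @param bin_edges Common bin grid.
#' @param n_boot Number of bootstrap replicates (>= 2; default 100).
#' @param seed Integer seed for the resampling.
#' @param reference_region Region passed to [set_reference()] for the
#'   point estimate and every replicate (errors are only meaningful in a
#'   fixed gauge). Default: outermost 10% of the grid.
#' @param discard_fraction,tol,max_iter Passed through.
#' @return The referenced point-estimate `free_energy_profile` with
#'   bootstrap `stderr`; `$details$n_boot_failed` counts replicates that
#'   failed to converge (reported, not silently dropped).
#' @export
bootstrap_error <- function(trajectories, bin_edges, n_boot = 100, seed = 1,
                            reference_region = NULL, discard_fraction = 0.1,
                            tol = 1e-7, max_iter = 1e5) {
  stopifnot(n_boot >= 2)
  hists <- histogram_windows(trajectories, bin_edges, discard_fraction)
  point <- wham(hists, tol = tol, max_iter = max_iter)
  if (is.null(reference_region)) reference_region <- vapor_region(point)
  point <- set_reference(point, reference_region)
  key <- vapply(hists, function(h)
    paste(h$bias$center, h$bias$force_constant), "")
  groups <- split(seq_along(hists), key)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  zkey <- round(point$z, 9)
  reps <- matrix(NA_real_, nrow = length(point$z), ncol = n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]))
    wb <- tryCatch(
      set_reference(wham(hists[idx], tol = tol, max_iter = max_iter),
                    reference_region),
      error = function(e) {
        warning("bootstrap replicate ", b, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(wb)) { failed <- failed + 1L; next }
    m <- match(zkey, round(wb$z, 9))
    reps[, b] <- wb$w[m]
  }
  ok <- !apply(is.na(reps), 2, all)
  se <- apply(reps[, ok, drop = FALSE], 1, sd, na.rm = TRUE)
  point$stderr <- se
  point$details$n_boot <- sum(ok)
  point$details$n_boot_failed <- failed
  point$details$boot_mean <- rowMeans(reps[, ok, drop = FALSE], na.rm = TRUE)
  point
}

#' Mean free energy over a region
#'
#' Unweighted mean of `w` over the profile bins falling in `region`; the
#' summary used to report average excess free energies of a solute inside
#' the slab.
#'
#' @param profile A `free_energy_profile`.
#' @param region Length-2 numeric (nm).
#' @return Scalar mean free energy (kJ/mol).
#' @export
average_free_energy <- function(profile, region) {
  stopifnot(inherits(profile, "free_energy_profile"),
            is.numeric(region), length(region) == 2)
  sel <- profile$z >= min(region) & profile$z <= max(region)
  if (!any(sel)) stop("region contains no profile bins")
  mean(profile$w[sel])
}

#' Symmetrize a profile about z = 0
#'
#' Replaces `w(z)` by `(w(z) + w(-z))/2` on a grid symmetric about the
#' slab centre; idempotent.
#'
#' @param profile A `free_energy_profile` whose grid is symmetric about 0
#'   (within tolerance).
#' @return The symmetrized profile.
#' @export
symmetrize <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  z <- profile$z
  m <- match(round(-z, 9), round(z, 9))
  if (any(is.na(m))) stop("grid is not symmetric about z = 0")
  profile$w <- (profile$w + profile$w[m]) / 2
  if (!is.null(profile$stderr))
    profile$stderr <- sqrt(profile$stderr^2 + profile$stderr[m]^2) / 2
  profile
}

#' Mirror a one-sided profile to the full slab
#'
#' Umbrella campaigns sample one half of an even slab; this reflects a
#' profile defined for `z >= 0` about the centre to produce the two-sided
#' profile used by the permeability integral.
#'
#' @param profile A `free_energy_profile` (or `diffusion_profile`) whose
#'   grid lies at `z >= -tol`.
#' @param tol Bins below `-tol` are an error; bins in `[-tol, 0)` are
#'   dropped.
#' @return The two-sided profile.
#' @export
mirror_profile <- function(profile, tol = 1e-9) {
  UseMethod("mirror_profile")
}

#' @export
mirror_profile.free_energy_profile <- function(profile, tol = 1e-9) {
  z <- profile$z
  if (min(z) < -max(tol, 0.25)) stop("profile is not one-sided")
  keep <- z >= -tol
  z <- z[keep]; w <- profile$w[keep]
  se <- if (!is.null(profile$stderr)) profile$stderr[keep]
  pos <- z > tol
  new_fe_profile(c(-rev(z[pos]), z), c(rev(w[pos]), w),
                 stderr = if (!is.null(se)) c(rev(se[pos]), se),
                 reference = profile$reference,
                 temperature = profile$temperature,
                 details = profile$details)
}
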