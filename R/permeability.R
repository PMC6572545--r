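## Inhomogeneous solubility-diffusion model:
##   1/Pm = int_{z1}^{z2} exp(w(z)/kBT) / D(z) dz
## Resistances of sub-intervals add; Pm is reported in m/s
## (1 nm/ps = 1e3 m/s).

interp_profile <- function(z, w, z_grid, what, extrapolate = FALSE) {
  rng <- range(z)
  outside <- z_grid < rng[1] - 1e-12 | z_grid > rng[2] + 1e-12
  if (any(outside)) {
    if (!extrapolate)
      stop(sprintf("integration grid extends beyond the %s profile support [%.4g, %.4g] nm",
                   what, rng[1], rng[2]))
    warning(sprintf("%s profile extrapolated as constant beyond [%.4g, %.4g] nm",
                    what, rng[1], rng[2]))
  }
  stats::approx(z, w, xout = z_grid, rule = 2)$y
}

#' Permeation resistance integrand
#'
#' `r(z) = exp(w(z)/kBT) / D(z)`, with both profiles linearly interpolated
#' onto `z_grid` and the ratio computed in log space. The free-energy
#' profile must cover the grid; the diffusion profile is extrapolated as
#' constant beyond its outermost centre (with a warning).
#'
#' @param fep A `free_energy_profile` (kJ/mol).
#' @param dprof A `diffusion_profile` (nm^2/ps).
#' @param z_grid Positions (nm).
#' @param temperature K; defaults to the free-energy profile's.
#' @return `data.frame(z, r)` with r in ps/nm^2.
#' @export
resistance_integrand <- function(fep, dprof, z_grid, temperature = NULL) {
  stopifnot(inherits(fep, "free_energy_profile"))
  if (is.null(temperature)) temperature <- fep$temperature
  w <- interp_profile(fep$z, fep$w, z_grid, "free-energy")
  D <- interp_profile(dprof$z, dprof$D, z_grid, "diffusion",
                      extrapolate = TRUE)
  if (any(D <= 0)) stop("non-positive diffusion coefficient on the grid")
  data.frame(z = z_grid, r = exp(w / kBT(temperature) - log(D)))
}

#' Permeability coefficient from profiles
#'
#' Trapezoidal evaluation of the solubility-diffusion integral on a
#' uniform grid. `range_mode = "interface"` integrates over the two
#' symmetric intervals `[-z2, -z1]` and `[z1, z2]` and sums their
#' resistances (a full crossing traverses both interfaces);
#' `"single"`/`"full"` integrate the one interval `[z1, z2]`.
#'
#' @param fep A `free_energy_profile` covering the requested range.
#' @param dprof A `diffusion_profile`.
#' @param z1,z2 Interval bounds in nm, `z1 < z2`.
#' @param range_mode `"single"`, `"full"`, or `"interface"`.
#' @param temperature K; defaults to the free-energy profile's.
#' @param dz Integration grid spacing (nm, default 0.01); at least 10
#'   points per interval are required.
#' @return Object of class `permeability_result` with `Pm` (m/s),
#'   `Pm_nm_ps`, `resistance` (s/m), `z_range`, `range_mode`,
#'   `temperature`, `grid_spacing`.
#' @export
permeability <- function(fep, dprof, z1, z2,
                         range_mode = c("single", "full", "interface"),
                         temperature = NULL, dz = 0.01) {
  range_mode <- match.arg(range_mode)
  stopifnot(is.numeric(z1), is.numeric(z2))
  if (z1 >= z2) stop("z1 must be < z2")
  if (is.null(temperature)) temperature <- fep$temperature
  intervals <- if (range_mode == "interface")
    list(c(-z2, -z1), c(z1, z2)) else list(c(z1, z2))
  R <- 0
  for (iv in intervals) {
    grid <- seq(iv[1], iv[2], by = dz)
    if (abs(grid[length(grid)] - iv[2]) > 1e-12) grid <- c(grid, iv[2])
    if (length(grid) < 10)
      stop("fewer than 10 grid points per interval: reduce dz")
    r <- resistance_integrand(fep, dprof, grid, temperature)
    R <- R + pracma::trapz(r$z, r$r)  # ps/nm
  }
  Pm_nm_ps <- 1 / R
  structure(list(Pm = Pm_nm_ps * NM_PS_TO_M_S, Pm_nm_ps = Pm_nm_ps,
                 resistance = 1 / (Pm_nm_ps * NM_PS_TO_M_S),
                 z_range = intervals, range_mode = range_mode,
                 temperature = temperature, grid_spacing = dz),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  iv <- paste(vapply(x$z_range, function(v)
    sprintf("[%.3g, %.3g]", v[1], v[2]), ""), collapse = " U ")
  cat(sprintf("<permeability: Pm = %.3g m/s over %s nm (%s, T = %g K)>\n",
              x$Pm, iv, x$range_mode, x$temperature))
  invisible(x)
}

#' Closed-form permeability of piecewise-constant profiles
#'
#' Exact solubility-diffusion integral for contiguous segments with
#' constant `w` and `D`: `1/Pm = sum length * exp(w/kBT) / D`. Serves as
#' the independent oracle for [permeability()].
#'
#' @param segments `data.frame` with columns `length` (nm, > 0), `w`
#'   (kJ/mol), `D` (nm^2/ps).
#' @param temperature K.
#' @return Pm in m/s.
#' @export
analytic_permeability <- function(segments, temperature) {
  stopifnot(is.data.frame(segments),
            all(c("length", "w", "D") %in% names(segments)))
  if (any(segments$length <= 0)) stop("zero-length segment")
  if (any(segments$D <= 0)) stop("non-positive diffusion coefficient")
  R <- sum(segments$length * exp(segments$w / kBT(temperature)) / segments$D)
  (1 / R) * NM_PS_TO_M_S
}

#' Permselectivity table
#'
#' Ratios `P_a / P_b` for every ordered pair of labelled permeability
#' coefficients; the diagonal is 1 and `S(a,b) S(b,a) = 1`.
#'
#' @param results Named list of `permeability_result` (which must share
#'   `range_mode` and temperature) or a named numeric vector of
#'   permeabilities in m/s.
#' @return Object of class `selectivity_table`: `data.frame(a, b, ratio,
#'   ratio_3sf)`; printed to 3 significant figures.
#' @export
selectivity <- function(results) {
  if (is.list(results) && all(vapply(results, inherits, TRUE,
                                     "permeability_result"))) {
    modes <- unique(vapply(results, `[[`, "", "range_mode"))
    temps <- unique(vapply(results, `[[`, 0, "temperature"))
    if (length(modes) > 1) stop("cannot mix range modes in a selectivity table")
    if (length(temps) > 1) stop("cannot mix temperatures in a selectivity table")
    P <- vapply(results, `[[`, 0, "Pm")
  } else {
    P <- unlist(results)
  }
  if (is.null(names(P)) || any(names(P) == ""))
    stop("permeabilities must be named by solute")
  if (any(P <= 0)) stop("permeabilities must be positive")
  pairs <- expand.grid(b = names(P), a = names(P), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)[, c("a", "b")]
  ratio <- P[pairs$a] / P[pairs$b]
  structure(data.frame(a = pairs$a, b = pairs$b, ratio = as.numeric(ratio),
                       ratio_3sf = signif(as.numeric(ratio), 3),
                       row.names = NULL),
            class = c("selectivity_table", "data.frame"))
}

#' @export
print.selectivity_table <- function(x, ...) {
  cat("Permselectivity (P_a / P_b, 3 s.f.):\n")
  print.data.frame(data.frame(a = x$a, b = x$b,
                              ratio = format(x$ratio_3sf, digits = 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Look up one ratio in a selectivity table
#'
#' @param table A `selectivity_table`.
#' @param a,b Solute labels.
#' @return The ratio `P_a / P_b` (full precision).
#' @export
selectivity_ratio <- function(table, a, b) {
  i <- which(table$a == a & table$b == b)
  if (length(i) != 1) stop("pair not found in table")
  table$ratio[i]
}
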