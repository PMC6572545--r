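## Parametric slab models: ground-truth free energy w(z), local diffusion
## coefficient D(z) and mass density rho(z) for a liquid slab centred at
## z = 0 with liquid-vapor interfaces at |z| = slab_half_width. All three
## profiles are even in z and have closed-form derivatives:
##
##   w(z)   = plateau * q(z; h_w, s_w)/q(0) + well * [g(z - z_int) + g(z + z_int)]
##   D(z)   = D_vapor + (D_bulk - D_vapor) * q(z; h_w, s_D)/q(0)
##   rho(z) = rho_bulk * t(z; h_w, s_rho)/t(0)
##
## with q the product of two logistic sigmoids (a smoothed plateau), g a
## Gaussian well of width s_w at the interface, and t the matching tanh
## plateau. The vapor phase (|z| -> box edge) is the w = 0 reference.

logistic <- function(x) plogis(x)

## smoothed plateau q(z) = sigma((h+z)/s) * sigma((h-z)/s) and d q / d z
plateau_shape <- function(z, h, s) {
  a <- logistic((h + z) / s)
  b <- logistic((h - z) / s)
  list(q = a * b,
       dq = (a * (1 - a) * b - a * b * (1 - b)) / s)
}

#' Construct a synthetic slab model
#'
#' Defines the ground truth for the synthetic umbrella-sampling generator:
#' an even free-energy profile with interfacial Gaussian wells and a
#' smoothed interior plateau, a sigmoid blend between the vapor and bulk
#' diffusion coefficients, and a tanh density profile. Internal units are
#' nm, ps, kJ/mol and K.
#'
#' @param pmf_params list with `well_depth` (Gaussian well amplitude at the
#'   interfaces, kJ/mol, typically negative), `plateau` (interior excess
#'   free energy, kJ/mol), `z_int` (interface position |z|, nm),
#'   `interface_width` (nm, width of both the wells and the plateau edge),
#'   `slab_half_width` (nm).
#' @param diff_params list with `d_vapor`, `d_bulk` (nm^2/ps, `d_vapor >=
#'   d_bulk`: diffusion is fastest where the liquid density is lowest) and
#'   `transition_width` (nm).
#' @param density_params list with `rho_bulk` (kg/m^3) and
#'   `interface_width` (nm).
#' @param temperature Temperature in K.
#' @param box_half_length Half-length of the box along z (nm); must exceed
#'   `slab_half_width + 3 * interface_width` so that the vapor reference
#'   region exists.
#' @param label Optional character tag carried into trajectory provenance.
#' @return An object of class `slab_model`.
#' @examples
#' m <- build_slab_model(
#'   pmf_params = list(well_depth = -2, plateau = 11.79, z_int = 2,
#'                     interface_width = 0.25, slab_half_width = 2),
#'   diff_params = list(d_vapor = 2.5e-3, d_bulk = 1e-3,
#'                      transition_width = 0.25),
#'   density_params = list(rho_bulk = 1100, interface_width = 0.3),
#'   temperature = 300, box_half_length = 7)
#' evaluate_model(m, c(0, 2, 7))
#' @export
build_slab_model <- function(pmf_params, diff_params, density_params,
                             temperature = 300, box_half_length = 7,
                             label = NULL) {
  p <- pmf_params; d <- diff_params; r <- density_params
  need <- function(l, f) all(f %in% names(l))
  if (!need(p, c("well_depth", "plateau", "z_int", "interface_width",
                 "slab_half_width")))
    stop("pmf_params incomplete")
  if (!need(d, c("d_vapor", "d_bulk", "transition_width")))
    stop("diff_params incomplete")
  if (!need(r, c("rho_bulk", "interface_width")))
    stop("density_params incomplete")
  if (p$interface_width <= 0 || d$transition_width <= 0 ||
      r$interface_width <= 0 || p$slab_half_width <= 0)
    stop("widths must be positive")
  if (d$d_vapor < 0 || d$d_bulk < 0)
    stop("diffusion coefficients must be non-negative")
  if (d$d_vapor < d$d_bulk)
    stop("d_vapor must be >= d_bulk (diffusion peaks in the low-density region)")
  if (r$rho_bulk < 0) stop("bulk density must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  if (box_half_length <= p$slab_half_width + 3 * p$interface_width)
    stop("box_half_length must exceed slab_half_width + 3*interface_width")
  m <- structure(
    list(pmf_params = p, diff_params = d, density_params = r,
         temperature = temperature, box_half_length = box_half_length),
    class = "slab_model")
  m$model_id <- fnv1a32(paste(
    if (is.null(label)) "slab" else label,
    paste(format(unlist(m[c("pmf_params", "diff_params", "density_params",
                            "temperature", "box_half_length")]),
                 digits = 17), collapse = ","),
    sep = ":"))
  if (!is.null(label)) m$label <- label
  ## sanity: vapor reference must actually be ~0 at the box edge
  edge <- evaluate_model(m, box_half_length)
  if (abs(edge$w) > 1e-6 * max(1, abs(p$plateau), abs(p$well_depth)))
    warning("w(box edge) = ", signif(edge$w, 3),
            " kJ/mol: vapor reference region is not flat; enlarge the box")
  m
}

#' Evaluate a slab model
#'
#' Returns the free energy, its analytic derivative, the diffusion
#' coefficient and its analytic derivative at positions `z`.
#'
#' @param model A `slab_model`.
#' @param z Positions in nm (vectorised); must lie within
#'   `[-box_half_length, box_half_length]`.
#' @return `data.frame(z, w, dwdz, D, dDdz)` with w in kJ/mol, D in nm^2/ps.
#' @export
evaluate_model <- function(model, z) {
  stopifnot(inherits(model, "slab_model"), is.numeric(z))
  L <- model$box_half_length
  if (any(abs(z) > L + 1e-12))
    stop("z outside the box [-", L, ", ", L, "] nm")
  p <- model$pmf_params; d <- model$diff_params
  h <- p$slab_half_width
  sw <- p$interface_width
  pw <- plateau_shape(z, h, sw)
  q0 <- plateau_shape(0, h, sw)$q
  gp <- exp(-(z - p$z_int)^2 / (2 * sw^2))
  gm <- exp(-(z + p$z_int)^2 / (2 * sw^2))
  w <- p$plateau * pw$q / q0 + p$well_depth * (gp + gm)
  dwdz <- p$plateau * pw$dq / q0 +
    p$well_depth * (-(z - p$z_int) / sw^2 * gp - (z + p$z_int) / sw^2 * gm)
  sd_ <- d$transition_width
  pd <- plateau_shape(z, h, sd_)
  qd0 <- plateau_shape(0, h, sd_)$q
  D <- d$d_vapor + (d$d_bulk - d$d_vapor) * pd$q / qd0
  dDdz <- (d$d_bulk - d$d_vapor) * pd$dq / qd0
  data.frame(z = z, w = w, dwdz = dwdz, D = D, dDdz = dDdz)
}

#' Mass density profile of a slab model
#'
#' Smooth tanh interface profile: bulk density inside the slab, zero in the
#' vapor phase, even in z.
#'
#' @param model A `slab_model`.
#' @param z_grid Positions in nm within the box.
#' @return `data.frame(z, density)` with density in kg/m^3.
#' @export
density_profile <- function(model, z_grid) {
  stopifnot(inherits(model, "slab_model"), is.numeric(z_grid))
  L <- model$box_half_length
  if (any(abs(z_grid) > L + 1e-12)) stop("grid outside the box")
  h <- model$pmf_params$slab_half_width
  s <- model$density_params$interface_width
  t_ <- 0.5 * (tanh((h + z_grid) / s) + tanh((h - z_grid) / s))
  t0 <- tanh(h / s)
  data.frame(z = z_grid, density = model$density_params$rho_bulk * t_ / t0)
}

#' @export
print.slab_model <- function(x, ...) {
  p <- x$pmf_params; d <- x$diff_params
  cat("<slab_model", x$model_id, if (!is.null(x$label)) x$label, ">\n")
  cat(sprintf("  w: plateau %.3g kJ/mol, wells %.3g kJ/mol at |z| = %.3g nm\n",
              p$plateau, p$well_depth, p$z_int))
  cat(sprintf("  D: %.3g (vapor) -> %.3g (bulk) nm^2/ps\n",
              d$d_vapor, d$d_bulk))
  cat(sprintf("  slab half-width %.3g nm, box half-length %.3g nm, T = %g K\n",
              p$slab_half_width, x$box_half_length, x$temperature))
  invisible(x)
}

## Tabulate dw/dz, D, dD/dz on a uniform grid for the compiled integrator.
## Resolution 0.001 nm: linear-interpolation error in the forces is far
## below the sampling noise at any feasible trajectory length.
model_tables <- function(model, dz = 0.001) {
  L <- model$box_half_length
  z <- seq(-L, L, by = dz)
  ev <- evaluate_model(model, z)
  list(z_lo = z[1], dz = dz, w = ev$w, wprime = ev$dwdz, D = ev$D,
       dprime = ev$dDdz)
}
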