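#' Generate an umbrella-sampling campaign
#'
#' Emulates the study protocol on a synthetic slab: `n_windows` restraint
#' centres separated by `window_spacing`, staggered over `n_offsets`
#' offset runs of `window_spacing / n_offsets`, giving
#' `n_windows * n_offsets` distinct centres at the fine effective spacing;
#' the whole ladder is repeated `n_replicates` times with independent
#' seeds so replicate free-energy and diffusion profiles can be averaged.
#' Defaults: 6 windows 1.0 nm apart staggered over 10 offsets (60 centres,
#' 0.1 nm apart), k = 2000 kJ/mol/nm^2, 4 ns per window, 25 replicates.
#'
#' @param model A `slab_model`.
#' @param window_spacing Spacing of the coarse window ladder (nm).
#' @param n_windows Number of windows per offset run.
#' @param n_offsets Number of staggered offset runs.
#' @param force_constant Restraint force constant (kJ/mol/nm^2).
#' @param n_steps Integration steps per window (default 4 ns at `dt`).
#' @param dt Integration time step (ps).
#' @param thin Output stride (sampling interval `thin * dt`).
#' @param n_replicates Independent repeats of the full ladder.
#' @param seed Master seed; per-trajectory seeds are derived
#'   deterministically from it and the (centre, replicate) indices.
#' @param z_min Centre of the first window (nm).
#' @return Object of class `us_campaign`: list with `trajectories` (one
#'   `window_trajectory` per centre x replicate), `meta` (data.frame with
#'   centre, force constant, replicate, seed), and the model.
#' @export
generate_us_campaign <- function(model, window_spacing = 1.0, n_windows = 6,
                                 n_offsets = 10, force_constant = 2000,
                                 n_steps = 400000, dt = 0.01, thin = 10,
                                 n_replicates = 25, seed = 1, z_min = 0) {
  stopifnot(inherits(model, "slab_model"))
  if (n_windows < 1 || n_offsets < 1 || n_replicates < 1)
    stop("empty campaign: n_windows, n_offsets and n_replicates must be >= 1")
  offsets <- (seq_len(n_offsets) - 1) * window_spacing / n_offsets
  centers <- sort(as.vector(outer((seq_len(n_windows) - 1) * window_spacing +
                                    z_min, offsets, `+`)))
  if (any(abs(centers) > model$box_half_length))
    stop("window centres extend beyond the box")
  eff <- if (length(centers) > 1) min(diff(centers)) else Inf
  sigma <- sqrt(kBT(model$temperature) / force_constant)
  if (is.finite(eff) && eff > 4 * sigma)
    warning(sprintf(
      "window spacing %.3g nm exceeds 4 window widths (sigma = %.3g nm): histograms may not overlap",
      eff, sigma))
  meta <- expand.grid(center = centers, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  meta$force_constant <- force_constant
  meta$window <- rep(seq_along(centers), times = n_replicates)
  meta$seed <- derive_seed(seed, meta$window, meta$replicate)
  trajectories <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    trajectories[[i]] <- simulate_langevin(
      model, bias_spec(meta$center[i], force_constant),
      n_steps = n_steps, dt = dt, seed = meta$seed[i], thin = thin)
  }
  structure(list(trajectories = trajectories, meta = meta, model = model,
                 protocol = list(window_spacing = window_spacing,
                                 n_windows = n_windows, n_offsets = n_offsets,
                                 force_constant = force_constant,
                                 n_steps = n_steps, dt = dt, thin = thin,
                                 n_replicates = n_replicates, seed = seed,
                                 z_min = z_min)),
            class = "us_campaign")
}

#' @export
print.us_campaign <- function(x, ...) {
  cat(sprintf(
    "<us_campaign: %d trajectories (%d centres x %d replicates), k = %g kJ/mol/nm^2>\n",
    length(x$trajectories), length(unique(x$meta$center)),
    max(x$meta$replicate), x$protocol$force_constant))
  invisible(x)
}

#' Split a campaign by replicate
#'
#' @param campaign A `us_campaign`.
#' @return List (one element per replicate) of lists of
#'   `window_trajectory`.
#' @export
campaign_replicates <- function(campaign) {
  stopifnot(inherits(campaign, "us_campaign"))
  lapply(split(seq_along(campaign$trajectories), campaign$meta$replicate),
         function(i) campaign$trajectories[i])
}
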