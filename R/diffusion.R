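#' Autocovariance of a restrained coordinate
#'
#' Mean-removed, unbiased-normalization autocovariance
#' `C(k dt) = sum_t (z_t - zbar)(z_{t+k} - zbar) / (n - k)` computed with
#' an FFT; `C(0)` equals the (denominator-n) sample variance to machine
#' precision.
#'
#' @param x A `window_trajectory` or numeric series.
#' @param max_lag Largest lag index (default `min(n %/% 10, 10000)`).
#' @param dt Sampling interval in ps (taken from the trajectory if given).
#' @return Object of class `autocovariance`: list with `lags` (ps,
#'   starting at 0), `C` (nm^2), `dt`, `n`.
#' @export
autocovariance <- function(x, max_lag = NULL, dt = NULL) {
  if (inherits(x, "window_trajectory")) {
    if (is.null(dt)) dt <- x$dt
    x <- x$samples
  }
  stopifnot(is.numeric(x), length(x) >= 2)
  if (is.null(dt)) dt <- 1
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n %/% 10, 10000)
  max_lag <- min(max_lag, n - 1)
  if (max_lag < 1) stop("max_lag must be >= 1 and < trajectory length")
  x <- x - mean(x)
  if (all(x == 0)) stop("constant trajectory: autocovariance is degenerate")
  m <- stats::nextn(2 * n)
  X <- fft(c(x, rep(0, m - n)))
  s <- Re(fft(Mod(X)^2, inverse = TRUE)) / m
  C <- s[seq_len(max_lag + 1)] / (n - 0:max_lag)
  structure(list(lags = (0:max_lag) * dt, C = C, dt = dt, n = n),
            class = "autocovariance")
}

#' Integral of the positional autocovariance
#'
#' Estimates `int_0^inf C(t) dt` by the trapezoidal rule. The default
#' truncates at the first zero crossing of C (linearly interpolated),
#' which is robust against the noisy tail; `"exp-tail"` fits
#' `C(t) = C0 exp(-t/tau)` over the initial decay and adds the analytic
#' tail beyond the fit window. If C never crosses zero within the
#' available lags, the full-range integral is returned with a warning.
#'
#' @param acov An `autocovariance` object.
#' @param method `"first-zero"` (default) or `"exp-tail"`.
#' @param tail_threshold For `"first-zero"`: also stop once C has decayed
#'   below this fraction of C(0) (default 0.01), if that happens before
#'   the crossing — the remaining exponential tail contributes ~1% while
#'   the accumulated tail noise can contribute far more. Set to 0 to
#'   truncate at the sign change only.
#' @return Scalar integral in nm^2 ps.
#' @export
correlation_integral <- function(acov, method = c("first-zero", "exp-tail"),
                                 tail_threshold = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(acov, "autocovariance"))
  t_ <- acov$lags; C <- acov$C; dt <- acov$dt
  cross <- which(C <= 0)[1]
  if (method == "first-zero") {
    decayed <- which(C <= tail_threshold * C[1])[1]
    cands <- c(cross, decayed)
    cands <- cands[!is.na(cands)]
    if (length(cands) == 0) {
      warning("no zero crossing within max_lag; integrating the full range")
      return(pracma::trapz(t_, C))
    }
    stop_at <- min(cands)
    if (stop_at == 1) return(0)
    j <- stop_at
    I <- pracma::trapz(t_[seq_len(j - 1)], C[seq_len(j - 1)])
    if (C[j] > 0) {
      ## stopped at the decay threshold: close with the last trapezoid
      I + 0.5 * (C[j - 1] + C[j]) * dt
    } else {
      ## triangle up to the interpolated crossing
      tstar <- t_[j - 1] + dt * C[j - 1] / (C[j - 1] - C[j])
      I + 0.5 * C[j - 1] * (tstar - t_[j - 1])
    }
  } else {
    ## fit the exponential decay over the range where C is positive and
    ## above 5% of C(0); integrate the fitted tail analytically
    lim <- if (is.na(cross)) length(C) else cross - 1
    sel <- seq_len(lim)
    sel <- sel[C[sel] > 0.05 * C[1]]
    if (length(sel) < 3) stop("too few points above the fit threshold")
    fit <- lm(log(C[sel]) ~ t_[sel])
    tau <- -1 / coef(fit)[[2]]
    if (!is.finite(tau) || tau <= 0)
      stop("exponential-tail fit produced a non-positive correlation time")
    tend <- t_[max(sel)]
    pracma::trapz(t_[seq_len(max(sel))], C[seq_len(max(sel))]) +
      C[max(sel)] * tau
  }
}

#' Local diffusion coefficient from a restrained window
#'
#' Positional-autocovariance estimator for a harmonically restrained,
#' equilibrated window: `D(z_i) = var(z)^2 / int_0^inf C_z(t) dt`, with
#' `z_i` the sample mean position. For an Ornstein-Uhlenbeck window the
#' identity is exact: `var = kBT/k`, `int C = var * tau`,
#' `tau = kBT/(k D)`.
#'
#' @param trajectory A `window_trajectory`.
#' @param max_lag,method Passed to [autocovariance()] /
#'   [correlation_integral()].
#' @param discard_fraction Initial fraction dropped as equilibration.
#' @return List with `z` (nm), `D` (nm^2/ps), `variance`, `integral`.
#' @export
diffusion_from_window <- function(trajectory, max_lag = NULL,
                                  method = "first-zero",
                                  discard_fraction = 0.1) {
  stopifnot(inherits(trajectory, "window_trajectory"))
  x <- trajectory$samples
  n0 <- floor(discard_fraction * length(x))
  if (n0 > 0) x <- x[-seq_len(n0)]
  acov <- autocovariance(x, max_lag = max_lag, dt = trajectory$dt)
  v <- acov$C[1]
  I <- correlation_integral(acov, method = method)
  if (!is.finite(I) || I <= 0)
    stop("non-positive correlation integral: window too short or undersampled")
  list(z = mean(x), D = v^2 / I, variance = v, integral = I)
}

#' Position-dependent diffusion profile from a campaign
#'
#' Applies [diffusion_from_window()] to every trajectory, groups the
#' estimates by restraint centre, and reports the per-centre mean and
#' standard error across replicates, sorted by z. Degenerate windows are
#' excluded with a warning.
#'
#' @param campaign A `us_campaign` or list of `window_trajectory`.
#' @param max_lag,method,discard_fraction Passed through.
#' @return Object of class `diffusion_profile`: list with `z` (nm), `D`
#'   (nm^2/ps), `D_m2s` (m^2/s), `stderr` (nm^2/ps), `n` (replicates per
#'   centre), `method`.
#' @export
diffusion_profile <- function(campaign, max_lag = NULL,
                              method = "first-zero",
                              discard_fraction = 0.1) {
  trajs <- if (inherits(campaign, "us_campaign")) campaign$trajectories
           else campaign
  stopifnot(length(trajs) >= 1)
  est <- lapply(seq_along(trajs), function(i) {
    tryCatch(
      c(center = trajs[[i]]$bias$center,
        unlist(diffusion_from_window(trajs[[i]], max_lag = max_lag,
                                     method = method,
                                     discard_fraction = discard_fraction)
               [c("z", "D")])),
      error = function(e) {
        warning("window ", i, " (centre ", trajs[[i]]$bias$center,
                " nm) excluded: ", conditionMessage(e))
        NULL
      })
  })
  est <- do.call(rbind, est[!vapply(est, is.null, TRUE)])
  if (is.null(est) || nrow(est) == 0) stop("no usable windows")
  g <- split(as.data.frame(est), est[, "center"])
  agg <- do.call(rbind, lapply(g, function(d) {
    data.frame(z = mean(d$z), D = mean(d$D),
               stderr = if (nrow(d) > 1) sd(d$D) / sqrt(nrow(d)) else 0,
               n = nrow(d))
  }))
  agg <- agg[order(agg$z), ]
  structure(list(z = agg$z, D = agg$D, D_m2s = agg$D * NM2_PS_TO_M2_S,
                 stderr = agg$stderr, n = agg$n, method = "acf"),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf(
    "<diffusion_profile (%s): %d centres, z in [%.3g, %.3g] nm, D in [%.3g, %.3g] nm^2/ps>\n",
    x$method, length(x$z), min(x$z), max(x$z), min(x$D), max(x$D)))
  invisible(x)
}

#' @export
as.data.frame.diffusion_profile <- function(x, ...) {
  data.frame(z = x$z, D_nm2_ps = x$D, D_m2_s = x$D_m2s, stderr = x$stderr,
             n = x$n)
}

#' @export
mirror_profile.diffusion_profile <- function(profile, tol = 1e-9) {
  z <- profile$z
  keep <- z >= -tol
  z <- z[keep]
  f <- function(v) v[keep]
  pos <- z > tol
  two <- function(v) c(rev(v[pos]), v)
  structure(list(z = c(-rev(z[pos]), z), D = two(f(profile$D)),
                 D_m2s = two(f(profile$D_m2s)),
                 stderr = two(f(profile$stderr)), n = two(f(profile$n)),
                 method = profile$method),
            class = "diffusion_profile")
}

## all-origin MSD of one coordinate via the FFT identity
## MSD(k) = [S1(k) - 2 S2(k)] / (n - k),
## S2(k) = sum_t x_t x_{t+k} (raw autocorrelation sums),
## S1(k) = sum_{t<n-k} (x_t^2 + x_{t+k}^2).
msd_1d <- function(x, max_lag) {
  n <- length(x)
  m <- stats::nextn(2 * n)
  X <- fft(c(x, rep(0, m - n)))
  s2 <- Re(fft(Mod(X)^2, inverse = TRUE))[seq_len(max_lag + 1)] / m
  q <- x^2
  cs <- c(0, cumsum(q))
  Q <- cs[n + 1]
  k <- 0:max_lag
  S1 <- (cs[n - k + 1]) + (Q - cs[k + 1])
  (S1 - 2 * s2) / (n - k)
}

#' Bulk diffusion from mean square displacement
#'
#' All-time-origin MSD of an unbiased 3-D trajectory and the Einstein
#' relation `MSD(t) = 6 D t`: D is the least-squares slope over the fit
#' window divided by 6.
#'
#' @param traj3d A `trajectory3d`.
#' @param fit_window Fractions of `max_lag` bounding the fitted lag range
#'   (default `c(0.1, 0.5)`; upper end must be in (0, 0.5] — beyond half
#'   the trajectory the MSD is too noisy to fit).
#' @param max_lag Largest lag index (default `n %/% 10`).
#' @return List with `D` (nm^2/ps), `lags` (ps), `msd` (nm^2), and the
#'   fitted slope.
#' @export
msd_diffusion <- function(traj3d, fit_window = c(0.1, 0.5), max_lag = NULL) {
  stopifnot(inherits(traj3d, "trajectory3d"),
            length(fit_window) == 2, fit_window[1] >= 0,
            fit_window[2] > fit_window[1], fit_window[2] <= 0.5 + 1e-12)
  n <- nrow(traj3d$samples)
  if (is.null(max_lag)) max_lag <- n %/% 10
  max_lag <- min(max_lag, n - 1)
  msd <- msd_1d(traj3d$samples[, 1], max_lag) +
    msd_1d(traj3d$samples[, 2], max_lag) +
    msd_1d(traj3d$samples[, 3], max_lag)
  lags <- (0:max_lag) * traj3d$dt
  ## fit window expressed as fractions of max_lag
  sel <- which(0:max_lag >= fit_window[1] * max_lag &
                 0:max_lag <= fit_window[2] * max_lag)
  if (length(sel) < 10) stop("fewer than 10 lags in the fit window")
  fit <- lm(msd[sel] ~ lags[sel])
  list(D = coef(fit)[[2]] / 6, slope = coef(fit)[[2]],
       lags = lags, msd = msd, fit_lags = lags[sel])
}
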