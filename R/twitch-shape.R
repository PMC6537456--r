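#' Evoked-twitch waveform family
#'
#' The generator renders evoked twitches with a three-parameter
#' rise-and-decay family,
#'
#'   g(tau) = (1 - exp(-tau/tau_r))^n_rise * exp(-tau/tau_d),
#'
#' normalized to unit peak.  The three degrees of freedom (rise time
#' constant tau_r, decay time constant tau_d, rise exponent n_rise) let the
#' waveform match a target contraction time (onset to peak), half
#' relaxation time (peak to half decay) and peak normalized slope
#' independently.  `twitch_waveform` evaluates the normalized waveform,
#' `twitch_shape_metrics` computes its (CT, HRT, peak slope) summary.
#'
#' Internally the solver works in time units of CT (peak fixed at tau = 1),
#' which removes one parameter: the peak condition g'(1) = 0 determines
#' tau_d from (tau_r, n_rise).
#'
#' @param tau Time since torque onset, ms (vector).
#' @param shape A \code{"twitch_shape"} object from [solve_twitch_shape()],
#'   or a list with elements \code{tau_r}, \code{tau_d}, \code{n_rise} (ms).
#' @return `twitch_waveform`: normalized torque values (peak = 1 at
#'   tau = CT).
#' @export
twitch_waveform <- function(tau, shape) {
  g <- shape_g(tau / shape$CT, shape$a, shape$n_rise, shape$d)
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- g[pos] / shape$g_peak
  out
}

# normalized-time primitives: a = tau_r/CT, d = tau_d/CT, peak at tau' = 1
shape_d_from <- function(a, n) a * (1 - exp(-1 / a)) / (n * exp(-1 / a))
shape_g <- function(taun, a, n, d) {
  g <- numeric(length(taun))
  pos <- taun > 0
  g[pos] <- (1 - exp(-taun[pos] / a))^n * exp(-taun[pos] / d)
  g
}
shape_gprime <- function(taun, a, n, d) {
  e <- exp(-taun / a)
  (1 - e)^(n - 1) * exp(-taun / d) * (n * e / a - (1 - e) / d)
}

# half-relaxation time (units of CT) of the normalized shape
shape_hrt <- function(a, n, d = shape_d_from(a, n)) {
  gp <- shape_g(1, a, n, d)
  f <- function(x) shape_g(x, a, n, d) - gp / 2
  up <- 1 + 40 * d
  if (f(up) > 0) return(Inf)
  stats::uniroot(f, c(1, up), tol = 1e-10)$root - 1
}

# peak normalized slope (units of 1/CT) of the normalized shape, using
# the measurement definition: sampled at step dt (CT units), 5-sample
# moving average, central difference.  Defining the solver's slope
# functional as what the pipeline measures makes rendered twitches
# reproduce the target MRTD at the recording's own resolution; a dense
# analytic maximum would overstate it for sharply rising shapes whose
# derivative peak is narrower than the smoothing window.
shape_slope <- function(a, n, d = shape_d_from(a, n), dt = 0.0105,
                        smooth_n = 5) {
  # leading pre-onset zeros so the smoothing window is fully defined at
  # the onset, exactly as on a rendered trace
  taun <- seq(-(smooth_n - 1) * dt, 1.5, by = dt)
  g <- shape_g(taun, a, n, d)
  sm <- stats::filter(g, rep(1 / smooth_n, smooth_n), sides = 2)
  m <- length(sm)
  der <- (sm[-(1:2)] - sm[-((m - 1):m)]) / (2 * dt)
  max(der, na.rm = TRUE) / max(g)
}

# scan the rise-exponent grid for a given (CT, HRT): for each n, the a
# that matches the half-relaxation ratio (h strictly decreasing in a),
# and the peak normalized slope attained there
shape_scan <- function(CT, HRT, rate = 2000, smooth_n = 5) {
  dt <- (1000 / rate) / CT   # sample step in CT units
  h_t <- HRT / CT
  a_lo <- max(0.015, 1 / CT)    # tau_r within [1, 100] ms
  a_hi <- min(6, 100 / CT)
  a_for_h <- function(n) {
    f <- function(a) {
      h <- shape_hrt(a, n)
      if (is.infinite(h)) h <- 1e6
      h - h_t
    }
    flo <- f(a_lo); fhi <- f(a_hi)
    if (flo < 0 || fhi > 0) return(NA_real_)
    stats::uniroot(f, c(a_lo, a_hi), tol = 1e-9)$root
  }
  n_grid <- exp(seq(log(0.5), log(4), length.out = 13))
  a_grid <- vapply(n_grid, a_for_h, numeric(1))
  ok <- !is.na(a_grid)
  if (!any(ok))
    stop("infeasible shape: no parameters within bounds match CT and HRT")
  s_grid <- rep(NA_real_, length(n_grid))
  s_grid[ok] <- mapply(function(a, n)
    shape_slope(a, n, dt = dt, smooth_n = smooth_n),
    a_grid[ok], n_grid[ok])
  list(n_grid = n_grid, a_grid = a_grid, s_grid = s_grid, ok = ok,
       a_for_h = a_for_h, dt = dt, smooth_n = smooth_n)
}

#' Attainable band of the twitch peak normalized slope
#'
#' Range of peak normalized slopes (MRTD / P, in 1/ms) the waveform
#' family can achieve while matching the given contraction and half
#' relaxation times.  No unimodal waveform peaking at CT can have a
#' maximal slope below its mean slope 1/CT; within this family the floor
#' is about 1.7--2.2/CT, and the ceiling shrinks towards it as HRT/CT
#' decreases (a sharply relaxing twitch cannot rise arbitrarily steeply
#' while still peaking at CT).  The generator uses this band to keep
#' drawn MRTD trajectories renderable.
#'
#' Slopes follow the measurement definition (sampled, smoothed, central
#' difference), so the band is the range the extraction pipeline can
#' actually read back at the given sampling rate.
#'
#' @param CT Contraction time, ms.
#' @param HRT Half relaxation time, ms.
#' @param rate Sampling rate of the rendered signal, Hz.
#' @param smooth_n Moving-average window of the derivative, samples.
#' @return Numeric vector \code{c(lo, hi)}: attainable \code{mrtd_norm}
#'   range, 1/ms (slightly shrunk so band endpoints remain solvable).
#' @export
twitch_slope_band <- function(CT, HRT, rate = 2000, smooth_n = 5) {
  scan <- shape_scan(CT, HRT, rate, smooth_n)
  s <- scan$s_grid[scan$ok]
  lo <- 1.002 * min(s); hi <- 0.998 * max(s)
  if (lo > hi) lo <- hi <- sqrt(min(s) * max(s))  # near-point band
  c(lo, hi) / CT
}

#' Solve twitch shape parameters for target contractile metrics
#'
#' Finds (tau_r, tau_d, n_rise) such that the rendered waveform has
#' time-to-peak CT, half-decay time HRT and peak normalized slope
#' mrtd_norm (the maximal rate of torque development divided by peak
#' torque, in 1/ms).  CT and HRT are always matched exactly (to solver
#' tolerance); if no rise exponent in [0.5, 4] reaches the requested peak
#' slope, the closest attainable slope is used and the result is flagged
#' \code{feasible = FALSE} with a warning (any unimodal waveform peaking at
#' CT has a normalized peak slope of at least 1/CT, so targets below that
#' are unattainable in principle).
#'
#' The slope functional is the measurement definition itself -- the
#' waveform sampled at \code{rate}, smoothed with a \code{smooth_n}-sample
#' moving average and differentiated by central differences -- so a
#' rendered twitch reproduces the target MRTD at the recording's own
#' resolution.
#'
#' @param CT Contraction time, ms (> 0).
#' @param HRT Half relaxation time, ms (> 0).
#' @param mrtd_norm Target peak normalized slope, 1/ms; must exceed the
#'   feasibility floor 0.3/CT.
#' @param rate Sampling rate of the rendered signal, Hz.
#' @param smooth_n Moving-average window of the derivative, samples.
#' @param warn Emit a warning when the slope target is unattainable.
#' @return An object of class \code{"twitch_shape"}: list with
#'   \code{tau_r}, \code{tau_d}, \code{n_rise} (ms-scale parameters),
#'   achieved \code{CT}, \code{HRT}, \code{mrtd_norm}, and
#'   \code{feasible}.
#' @export
solve_twitch_shape <- function(CT, HRT, mrtd_norm, rate = 2000,
                               smooth_n = 5, warn = TRUE) {
  stopifnot(CT > 0, HRT > 0)
  if (mrtd_norm <= 0.3 / CT)
    stop("infeasible shape: mrtd_norm below the 0.3/CT feasibility floor")
  s_t <- mrtd_norm * CT
  scan <- shape_scan(CT, HRT, rate, smooth_n)
  n_grid <- scan$n_grid; a_grid <- scan$a_grid
  s_grid <- scan$s_grid; ok <- scan$ok
  a_for_h <- scan$a_for_h

  resid <- s_grid - s_t
  feasible <- TRUE
  idx <- which(ok)
  cross <- idx[which(diff(sign(resid[idx])) != 0)]
  if (length(cross) > 0) {
    j <- cross[1]
    fr <- function(n) shape_slope(a_for_h(n), n, dt = scan$dt,
                                  smooth_n = smooth_n) - s_t
    n_sol <- stats::uniroot(fr, c(n_grid[j], n_grid[j + 1]), tol = 1e-7)$root
  } else {
    feasible <- FALSE
    n_sol <- n_grid[idx[which.min(abs(resid[idx]))]]
    if (warn)
      warning(sprintf(
        "twitch slope target %.4g/ms unattainable for CT=%.3g, HRT=%.3g; using closest %.4g/ms",
        mrtd_norm, CT, HRT,
        (s_t + resid[idx[which.min(abs(resid[idx]))]]) / CT))
  }
  a_sol <- a_for_h(n_sol)
  d_sol <- shape_d_from(a_sol, n_sol)
  if (d_sol * CT < 10 || d_sol * CT > 500)
    stop("infeasible shape: decay constant outside [10, 500] ms")
  shape <- list(
    tau_r = a_sol * CT, tau_d = d_sol * CT, n_rise = n_sol,
    a = a_sol, d = d_sol,
    CT = CT,
    HRT = shape_hrt(a_sol, n_sol, d_sol) * CT,
    mrtd_norm = shape_slope(a_sol, n_sol, d_sol, dt = scan$dt,
                            smooth_n = smooth_n) / CT,
    g_peak = shape_g(1, a_sol, n_sol, d_sol),
    rate = rate, smooth_n = smooth_n,
    feasible = feasible
  )
  class(shape) <- "twitch_shape"
  shape
}

#' @rdname solve_twitch_shape
#' @param shape A \code{"twitch_shape"} object.
#' @return `twitch_shape_metrics`: list with the waveform's achieved
#'   \code{CT} (ms), \code{HRT} (ms) and \code{mrtd_norm} (1/ms).
#' @export
twitch_shape_metrics <- function(shape) {
  list(CT = shape$CT,
       HRT = shape_hrt(shape$a, shape$n_rise, shape$d) * shape$CT,
       mrtd_norm = shape_slope(shape$a, shape$n_rise, shape$d,
                               dt = (1000 / shape$rate) / shape$CT,
                               smooth_n = shape$smooth_n) / shape$CT)
}

#' @export
print.twitch_shape <- function(x, ...) {
  cat(sprintf(
    "twitch shape: tau_r=%.2f ms, tau_d=%.2f ms, n_rise=%.3f (CT=%.1f, HRT=%.1f, peak slope=%.4f/ms%s)\n",
    x$tau_r, x$tau_d, x$n_rise, x$CT, x$HRT, x$mrtd_norm,
    if (x$feasible) "" else ", slope best-effort"))
  invisible(x)
}
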