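#' MVC peak torque
#'
#' Maximum torque over the voluntary-contraction window.  Samples within
#' a guard interval around superimposed stimuli are excluded so the evoked
#' increment is not counted as voluntary torque, and the window ends
#' shortly before the first resting stimulation so evoked responses to the
#' relaxed muscle are never included.
#'
#' @param trace A [torque_trace()].
#' @param guard_ms Guard half-width around superimposed stimuli, ms.
#' @return Peak voluntary torque, Nm.
#' @export
mvc_peak <- function(trace, guard_ms = 150) {
  if (length(trace$samples) == 0) stop("empty input: trace has no samples")
  t <- trace_times(trace)
  keep <- rep(TRUE, length(t))
  ev <- trace$events
  rest <- ev$time[ev$context == "resting"]
  if (length(rest) > 0) keep <- keep & (t < min(rest) - 0.5)
  sup <- ev$time[ev$context == "superimposed"]
  for (s in sup) {
    # the guard extends further after the stimulus than before it because
    # the evoked increment's relaxation (hundreds of ms) outlasts its rise
    keep <- keep & !(t >= s - guard_ms / 1000 & t <= s + 1.0)
  }
  if (!any(keep)) stop("empty input: no samples in the voluntary window")
  max(trace$samples[keep])
}

#' Torque onset detection after a stimulus
#'
#' Detects the mechanical response onset: the first post-stimulus sample
#' exceeding baseline mean + max(3 x baseline SD, 0.5% of the evoked
#' peak), back-tracked to the last sample at or below the baseline mean.
#' Resolution is one sample.
#'
#' @param trace A [torque_trace()].
#' @param stim_time Stimulus time, s; at least 100 ms of pre-stimulus
#'   baseline must be available.
#' @param search_ms Window after the stimulus within which a crossing must
#'   occur, ms.
#' @return Onset time, s.
#' @export
detect_onset <- function(trace, stim_time, search_ms = 150) {
  if (stim_time - trace$t0 < 0.1)
    stop("insufficient baseline: need >= 100 ms before the stimulus")
  base <- trace$samples[trace_window_idx(trace, stim_time - 0.1,
                                         stim_time - 1e-9)]
  b <- mean(base); s <- stats::sd(base)
  post <- trace_window_idx(trace, stim_time, stim_time + 0.5)
  peak <- max(trace$samples[post]) - b
  if (peak <= 0) stop("no-response error: no evoked torque above baseline")
  thr <- b + max(3 * s, 0.005 * peak)
  search <- trace_window_idx(trace, stim_time, stim_time + search_ms / 1000)
  above <- trace$samples[search] > thr
  # the crossing must be sustained (5 ms) -- a rising evoked response
  # stays above threshold, an isolated baseline noise spike does not
  run <- min(10, length(above))
  sustained <- which(vapply(seq_len(length(above) - run + 1), function(j)
    all(above[j:(j + run - 1)]), logical(1)))
  if (length(sustained) == 0)
    stop("no-response error: no sustained threshold crossing after the stimulus")
  i <- search[sustained[1]]
  while (i > search[1] && trace$samples[i - 1] > b) i <- i - 1
  # onset = the rising-side sample of the last baseline crossing; the
  # last at-baseline sample itself is biased early under noise (the
  # walk-back stops at whichever noise sample dips below the mean)
  trace$t0 + (i - 1) / trace$rate
}

#' Evoked twitch contractile properties
#'
#' Extracts the six electromechanical properties of a single evoked twitch
#' delivered to the relaxed muscle: peak torque (P, above the pre-stimulus
#' baseline), electromechanical delay (EMD, stimulus to onset),
#' contraction time (CT, onset to peak), half relaxation time (HRT, peak
#' to half decay), and the maximal rates of torque development (MRTD) and
#' relaxation (MRTR) as the extrema of the smoothed first derivative
#' (central difference after a 5-sample moving average).  MRTD and MRTR
#' are reported raw in Nm/ms; peak-normalized variants (1/ms) are stored
#' as \code{mrtd_norm}/\code{mrtr_norm}.
#'
#' @param trace A [torque_trace()].
#' @param stim_time Stimulus time, s.
#' @param smooth_n Moving-average window for the derivative, samples.
#' @return A list of class \code{"twitch_properties"}.
#' @export
twitch_properties <- function(trace, stim_time, smooth_n = 5) {
  onset <- detect_onset(trace, stim_time)
  base <- trace$samples[trace_window_idx(trace, stim_time - 0.1,
                                         stim_time - 1e-9)]
  b <- mean(base)
  t <- trace_times(trace)
  seg <- trace_window_idx(trace, onset,
                          min(onset + 1.0, t[length(t)]))
  ipk <- seg[which.max(trace$samples[seg])]
  P <- trace$samples[ipk] - b
  t_peak <- t[ipk]
  CT <- (t_peak - onset) * 1000
  # half relaxation: first drop below baseline + P/2 within 500 ms of peak
  half_win <- trace_window_idx(trace, t_peak,
                               min(t_peak + 0.5, t[length(t)]))
  below <- which(trace$samples[half_win] < b + P / 2)
  if (length(below) == 0)
    stop("unresolved HRT: torque does not fall below half-peak within 500 ms")
  HRT <- (t[half_win[below[1]]] - t_peak) * 1000

  # smoothed derivative over the twitch span
  span <- trace_window_idx(trace, stim_time,
                           min(t_peak + 0.5, t[length(t)]))
  y <- trace$samples[span]
  sm <- stats::filter(y, rep(1 / smooth_n, smooth_n), sides = 2)
  dt_ms <- 1000 / trace$rate
  d <- (sm[-(1:2)] - sm[-((length(sm) - 1):length(sm))]) / (2 * dt_ms)
  d <- d[is.finite(d)]
  MRTD <- max(d)
  MRTR <- max(-d)

  structure(list(P = P, EMD = (onset - stim_time) * 1000, CT = CT,
                 HRT = HRT, MRTD = MRTD, MRTR = MRTR,
                 mrtd_norm = MRTD / P, mrtr_norm = MRTR / P,
                 onset_time = onset, peak_time = t_peak),
            class = "twitch_properties")
}

#' @export
print.twitch_properties <- function(x, ...) {
  cat(sprintf(
    "twitch: P=%.2f Nm, EMD=%.1f ms, CT=%.1f ms, HRT=%.1f ms, MRTD=%.3f Nm/ms, MRTR=%.3f Nm/ms\n",
    x$P, x$EMD, x$CT, x$HRT, x$MRTD, x$MRTR))
  invisible(x)
}

#' Evoked doublet amplitude
#'
#' Amplitude of a 100-Hz doublet response.  For a resting doublet the
#' amplitude is the evoked peak minus the pre-stimulus baseline (25-ms
#' mean); for a superimposed doublet it is the peak within 200 ms of the
#' stimulus minus the voluntary torque level immediately pre-stimulus
#' (25-ms mean).
#'
#' @param trace A [torque_trace()].
#' @param stim_time Stimulus time, s; must be >= 25 ms after trace start.
#' @param context \code{"resting"} or \code{"superimposed"}.
#' @return Amplitude, Nm.
#' @export
doublet_amplitude <- function(trace, stim_time,
                              context = c("resting", "superimposed")) {
  context <- match.arg(context)
  if (stim_time - trace$t0 < 0.025)
    stop("insufficient baseline: stimulus < 25 ms from trace start")
  b <- mean(trace$samples[trace_window_idx(trace, stim_time - 0.025,
                                           stim_time - 1e-9)])
  win_s <- if (context == "superimposed") 0.2 else 0.3
  t_end <- trace$t0 + (length(trace$samples) - 1) / trace$rate
  win <- trace_window_idx(trace, stim_time, min(stim_time + win_s, t_end))
  max(trace$samples[win]) - b
}

#' Voluntary activation level (interpolated-twitch technique)
#'
#' VAL = (1 - Db_superimposed / Db_potentiated) x 100, clamped to
#' \code{[0, 100]}: the completeness of voluntary neural drive estimated
#' from the superimposed versus potentiated 100-Hz doublet amplitudes.
#'
#' @param db_superimposed Superimposed doublet amplitude, Nm (>= 0).
#' @param db_potentiated Potentiated resting doublet amplitude, Nm (> 0).
#' @return VAL in percent.
#' @export
compute_val <- function(db_superimposed, db_potentiated) {
  if (db_potentiated <= 0)
    stop("invalid denominator: potentiated doublet amplitude must be > 0")
  val <- (1 - db_superimposed / db_potentiated) * 100
  min(max(val, 0), 100)
}

#' Supramaximal stimulation intensity from a recruitment curve
#'
#' Finds the optimal stimulation intensity -- the lowest intensity from
#' which all subsequent response amplitudes stay within 2\% of the curve
#' maximum (plateau onset) -- and returns 130\% of it.  If the response is
#' still rising by more than the plateau tolerance at the last increment,
#' no plateau was reached.
#'
#' @param intensity Stimulation intensities, mA, strictly increasing.
#' @param amplitude Response amplitudes at each intensity.
#' @param plateau_tol Relative tolerance defining the plateau.
#' @param factor Supramaximal multiplier.
#' @return Supramaximal intensity, mA.
#' @export
supramaximal_intensity <- function(intensity, amplitude,
                                   plateau_tol = 0.02, factor = 1.3) {
  stopifnot(length(intensity) == length(amplitude), length(intensity) >= 2)
  if (is.unsorted(intensity, strictly = TRUE))
    stop("intensities must be strictly increasing")
  n <- length(amplitude)
  if ((amplitude[n] - amplitude[n - 1]) > plateau_tol * amplitude[n - 1])
    stop("no-plateau error: response still rising at the last increment")
  cmax <- max(amplitude)
  in_band <- amplitude >= (1 - plateau_tol) * cmax
  # lowest intensity from which every later amplitude stays in the band
  ok_from <- rev(cumprod(rev(in_band))) > 0
  factor * intensity[which(ok_from)[1]]
}
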