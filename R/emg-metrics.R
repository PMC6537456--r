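#' EMG root mean square over a window
#'
#' RMS of the EMG signal over a fixed window (default 0.5 s), used on the
#' MVC plateau before the superimposed stimulation.  The window must not
#' overlap a stimulus artifact (any stimulus pulse within 20 ms of the
#' window).
#'
#' @param trace An [emg_trace()].
#' @param window_start Window start, s.
#' @param window_len Window length, s.
#' @return RMS amplitude, mV.
#' @export
emg_rms <- function(trace, window_start, window_len = 0.5) {
  t_end <- trace$t0 + (length(trace$samples) - 1) / trace$rate
  if (window_start < trace$t0 || window_start + window_len > t_end + 1e-9)
    stop("window outside trace span")
  ev <- trace$events
  if (nrow(ev) > 0) {
    pulse_times <- unlist(lapply(seq_len(nrow(ev)), function(i) {
      ev$time[i] + (seq_len(ev$pulses[i]) - 1) * 0.01
    }))
    if (any(pulse_times > window_start - 0.02 &
            pulse_times < window_start + window_len + 0.02))
      stop("contaminated window: stimulus artifact within the RMS window")
  }
  idx <- trace_window_idx(trace, window_start, window_start + window_len)
  sqrt(mean(trace$samples[idx]^2))
}

#' M-wave peak-to-peak amplitude
#'
#' Maximum minus minimum of the EMG trace within 2--50 ms after the
#' stimulus, the span of the compound muscle action potential.
#'
#' @param trace An [emg_trace()].
#' @param stim_time Stimulus time, s.
#' @return Peak-to-peak amplitude, mV.
#' @export
mwave_p2p <- function(trace, stim_time) {
  t_end <- trace$t0 + (length(trace$samples) - 1) / trace$rate
  if (stim_time + 0.05 > t_end + 1e-9 || stim_time + 0.002 < trace$t0)
    stop("event-placement error: M-wave window exceeds trace span")
  idx <- trace_window_idx(trace, stim_time + 0.002, stim_time + 0.05)
  max(trace$samples[idx]) - min(trace$samples[idx])
}

#' EMG RMS normalized to the M-wave amplitude
#'
#' @param rms Voluntary EMG RMS, mV (>= 0).
#' @param mmax M-wave peak-to-peak amplitude, mV (> 0).
#' @return Dimensionless ratio (a.u.).
#' @export
normalized_rms <- function(rms, mmax) {
  if (mmax <= 0)
    stop("invalid denominator: M-wave amplitude must be > 0")
  rms / mmax
}

#' Relaxation check during an elastography scan
#'
#' Verifies that the muscle was relaxed during the resting scan: the mean
#' passive torque must stay strictly below \code{torque_thresh} and the
#' VL and BF EMG RMS strictly below \code{emg_thresh}.
#'
#' @param passive_torque_trace Passive torque [torque_trace()].
#' @param vl_trace,bf_trace Passive EMG traces.
#' @param torque_thresh Torque threshold, Nm.
#' @param emg_thresh EMG RMS threshold, mV.
#' @return List with \code{pass} (logical) and the measured levels
#'   \code{torque_mean}, \code{vl_rms}, \code{bf_rms}.
#' @export
check_relaxation <- function(passive_torque_trace, vl_trace, bf_trace,
                             torque_thresh = 2, emg_thresh = 0.01) {
  tq <- mean(passive_torque_trace$samples)
  vl <- sqrt(mean(vl_trace$samples^2))
  bf <- sqrt(mean(bf_trace$samples^2))
  list(pass = (tq < torque_thresh) && (vl < emg_thresh) && (bf < emg_thresh),
       torque_mean = tq, vl_rms = vl, bf_rms = bf)
}
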