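#' Protocol timing constants
#'
#' Timeline of one rendered measurement set, in seconds from trial start:
#' 250-ms torque ramp, 5-s MVC plateau, superimposed 100-Hz doublet 3 s
#' into the plateau, contraction release, potentiated 100-Hz doublet 3 s
#' after cessation, potentiated single twitch 3 s later.
#'
#' @return Named list of protocol times (s).
#' @export
protocol_timing <- function() {
  ramp <- 0.25; plateau <- 5.0; release <- 0.30
  list(
    ramp_dur = ramp,
    plateau_start = ramp,
    sup_doublet = ramp + 3.0,
    cessation = ramp + plateau,
    release_dur = release,
    pot_doublet = ramp + plateau + 3.0,
    pot_twitch = ramp + plateau + 6.0,
    trial_dur = ramp + plateau + 6.0 + 1.35,
    rms_window = c(ramp + 2.3, ramp + 2.8),
    doublet_ipi_ms = 10
  )
}

# normalized evoked waveform on a sample grid: zero before t_stim + EMD,
# then the twitch shape (1 pulse) or the sum of two shapes 10 ms apart
# (doublet), rescaled so the sampled maximum is exactly 1
evoked_component <- function(t, t_stim, emd_ms, shape, pulses = 1,
                             ipi_ms = 10) {
  tau <- (t - t_stim - emd_ms / 1000) * 1000
  v <- twitch_waveform(tau, shape)
  if (pulses == 2) v <- v + twitch_waveform(tau - ipi_ms, shape)
  mx <- max(v)
  if (mx > 0) v <- v / mx
  v
}

#' Render a potentiated single twitch torque trace
#'
#' Renders the torque response to a single supramaximal stimulus delivered
#' to the relaxed muscle: zero baseline until stimulus + EMD, then the
#' subject's twitch waveform scaled to peak torque P, plus additive
#' Gaussian torque noise.
#'
#' @param P Twitch peak torque, Nm (>= 0).
#' @param emd_ms Electromechanical delay, ms.
#' @param shape Twitch shape from [solve_twitch_shape()].
#' @param t_stim Stimulus time, s.
#' @param rate Sampling rate, Hz.
#' @param duration Trace duration, s.
#' @param noise_sd Additive torque noise SD, Nm.
#' @return A [torque_trace()] with a single resting stimulus event.
#' @export
render_twitch <- function(P, emd_ms, shape, t_stim = 0.5, rate = 2000,
                          duration = t_stim + 1.2, noise_sd = 0) {
  if (t_stim < 0 || t_stim > duration)
    stop("event-placement error: stimulus outside trace span")
  t <- seq(0, duration, by = 1 / rate)
  y <- if (P > 0) P * evoked_component(t, t_stim, emd_ms, shape) else numeric(length(t))
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  torque_trace(y, rate, events = data.frame(
    time = t_stim, kind = "single", context = "resting", pulses = 1L,
    stringsAsFactors = FALSE))
}

# raised-cosine voluntary torque envelope (0 outside the contraction)
voluntary_envelope <- function(t, level, timing) {
  env <- numeric(length(t))
  ramp <- t >= 0 & t < timing$ramp_dur
  env[ramp] <- level * 0.5 * (1 - cos(pi * t[ramp] / timing$ramp_dur))
  plat <- t >= timing$ramp_dur & t <= timing$cessation
  env[plat] <- level
  rel <- t > timing$cessation & t <= timing$cessation + timing$release_dur
  env[rel] <- level * 0.5 *
    (1 + cos(pi * (t[rel] - timing$cessation) / timing$release_dur))
  env
}

# biphasic M-wave wavelet with unit peak-to-peak amplitude, starting 5 ms
# after the stimulus, 30 ms long
mwave_wavelet <- function(t, t_stim) {
  tau <- t - t_stim - 0.005
  w <- numeric(length(t))
  act <- tau >= 0 & tau <= 0.03
  w[act] <- sin(2 * pi * 100 * tau[act]) * sin(pi * tau[act] / 0.03)^2
  p2p <- max(w) - min(w)
  if (p2p > 0) w <- w / p2p
  w
}

# band-limited (10-500 Hz) unit-scale EMG carrier noise
emg_carrier <- function(n, rate) {
  bf <- signal::butter(2, c(10, 500) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
}

#' Render one MVC trial with evoked stimulations
#'
#' Renders the full measurement set of one protocol time point: the
#' voluntary torque trace (ramp, 5-s plateau at the subject's MVC with a
#' superimposed 100-Hz doublet, release, then a potentiated doublet and a
#' potentiated single twitch delivered to the relaxed muscle) and the
#' matching VL EMG trace (band-limited interference noise at the target
#' plateau RMS plus an M-wave wavelet per stimulus pulse).
#'
#' The superimposed doublet increment has amplitude
#' \code{db_pot * (1 - VAL/100)}, the interpolated-twitch relation solved
#' for the increment.  The realized plateau level is
#' \code{MVC * (1 + Normal(0, plateau_cv))}.
#'
#' @param truth_t Named numeric vector: one subject's true values at this
#'   time point (needs \code{mvc}, \code{val}, \code{db_pot}, \code{tw_p},
#'   \code{emd}, \code{mmax}, \code{rms_mmax}, \code{vl_passive_rms}).
#' @param shape Twitch shape for this subject/time point.
#' @param config A [sim_config()].
#' @return List with elements \code{torque} ([torque_trace()]),
#'   \code{emg} ([emg_trace()]) and \code{events} (the stimulus table).
#' @export
render_mvc_trial <- function(truth_t, shape, config) {
  if (truth_t[["val"]] <= 0 || truth_t[["val"]] > 100)
    stop("invalid truth: VAL must be in (0, 100]")
  tm <- protocol_timing()
  rate <- config$sampling_rate
  t <- seq(0, tm$trial_dur, by = 1 / rate)
  noise <- config$noise

  level <- truth_t[["mvc"]] *
    (1 + stats::rnorm(1, 0, noise$plateau_cv))
  y <- voluntary_envelope(t, level, tm)

  emd <- truth_t[["emd"]]
  inc <- truth_t[["db_pot"]] * (1 - truth_t[["val"]] / 100)
  if (inc > 0)
    y <- y + inc * evoked_component(t, tm$sup_doublet, emd, shape, pulses = 2)
  y <- y + truth_t[["db_pot"]] *
    evoked_component(t, tm$pot_doublet, emd, shape, pulses = 2)
  y <- y + truth_t[["tw_p"]] *
    evoked_component(t, tm$pot_twitch, emd, shape, pulses = 1)
  if (noise$torque_sd > 0)
    y <- y + stats::rnorm(length(t), 0, noise$torque_sd)

  events <- data.frame(
    time = c(tm$sup_doublet, tm$pot_doublet, tm$pot_twitch),
    kind = c("doublet100Hz", "doublet100Hz", "single"),
    context = c("superimposed", "resting", "resting"),
    pulses = c(2L, 2L, 1L),
    stringsAsFactors = FALSE)

  # EMG: interference noise scaled to the target plateau RMS, passive
  # level outside the contraction, M-wave per stimulus pulse
  target_rms <- truth_t[["rms_mmax"]] * truth_t[["mmax"]]
  carrier <- emg_carrier(length(t), rate)
  # tolerant bounds so the normalization window matches the extraction
  # window sample-for-sample despite floating-point time stamps
  win <- t >= tm$rms_window[1] - 1e-9 & t <= tm$rms_window[2] + 1e-9
  carrier <- carrier / sqrt(mean(carrier[win]^2))
  amp <- pmax(target_rms * voluntary_envelope(t, 1, tm),
              truth_t[["vl_passive_rms"]])
  e <- carrier * amp
  ipi <- tm$doublet_ipi_ms / 1000
  pulse_times <- c(tm$sup_doublet, tm$sup_doublet + ipi,
                   tm$pot_doublet, tm$pot_doublet + ipi, tm$pot_twitch)
  for (pt in pulse_times)
    e <- e + truth_t[["mmax"]] * mwave_wavelet(t, pt)

  list(torque = torque_trace(y, rate, events = events),
       emg = emg_trace(e, rate, events = events, channel = "VL"),
       events = events)
}

#' Render a resting shear-wave elastography clip
#'
#' Renders frames of shear-wave speed (m/s): each pixel is
#' \code{sqrt(mu_true) + eta_frame + eps_pixel}, with a per-frame offset
#' \code{eta_frame ~ Normal(0, frame_speed_sd)} (probe/tissue state drift
#' between the 1-Hz acquisitions) and independent per-pixel noise
#' \code{eps_pixel ~ Normal(0, pixel_speed_sd)}.  Negative speeds are
#' clipped at zero.  The ROI is a centred square of
#' \code{config$roi_side} pixels.
#'
#' @param mu_true True shear elastic modulus, kPa (> 0).
#' @param config A [sim_config()].
#' @return An [swe_clip()].
#' @export
render_swe_clip <- function(mu_true, config) {
  if (mu_true <= 0) stop("invalid truth: mu_true must be > 0")
  vs <- sqrt(mu_true)
  nr <- config$map_shape[1]; nc <- config$map_shape[2]
  noise <- config$noise
  frames <- lapply(seq_len(config$n_frames), function(k) {
    eta <- if (noise$frame_speed_sd > 0)
      stats::rnorm(1, 0, noise$frame_speed_sd) else 0
    px <- if (noise$pixel_speed_sd > 0)
      stats::rnorm(nr * nc, 0, noise$pixel_speed_sd) else 0
    m <- matrix(vs + eta + px, nr, nc)
    m[m < 0] <- 0
    m
  })
  r0 <- (nr - config$roi_side) %/% 2
  c0 <- (nc - config$roi_side) %/% 2
  swe_clip(frames, pixel_mm = 1, frame_interval = config$frame_interval,
           roi = c(r0, c0, config$roi_side, config$roi_side))
}

#' Render the resting-scan monitoring traces
#'
#' Passive knee-extensor torque and VL/BF EMG recorded over the 5-s
#' elastography scan to verify the relaxed state.
#'
#' @param truth_t Named numeric vector of true values at this time point.
#' @param config A [sim_config()].
#' @param duration Scan duration, s.
#' @return List with \code{torque}, \code{vl}, \code{bf} traces.
#' @export
render_passive <- function(truth_t, config, duration = 5) {
  rate <- config$sampling_rate
  n <- length(seq(0, duration, by = 1 / rate))
  y <- rep(truth_t[["passive_torque"]], n)
  if (config$noise$torque_sd > 0)
    y <- y + stats::rnorm(n, 0, config$noise$torque_sd)
  mk_emg <- function(rms_target, channel) {
    car <- emg_carrier(n, rate)
    car <- car / sqrt(mean(car^2)) * rms_target
    emg_trace(car, rate, channel = channel)
  }
  list(torque = torque_trace(y, rate),
       vl = mk_emg(truth_t[["vl_passive_rms"]], "VL"),
       bf = mk_emg(truth_t[["bf_passive_rms"]], "BF"))
}
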