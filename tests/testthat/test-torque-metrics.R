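make_trace <- function(samples, rate = 2000, events = NULL) {
  torque_trace(samples, rate, events = events)
}

test_that("mvc_peak takes the plateau maximum and honours the guard", {
  rate <- 2000
  t <- seq(0, 4, by = 1 / rate)
  plateau <- rep(352, length(t))
  expect_equal(mvc_peak(make_trace(plateau)), 352)
  expect_equal(mvc_peak(make_trace(rep(0, 100))), 0)
  # a superimposed doublet reaching above the plateau inside the guard
  # must not be counted
  y <- rep(200, length(t))
  stim <- 2
  y[t >= stim & t <= stim + 0.1] <- 212
  ev <- data.frame(time = stim, kind = "doublet100Hz",
                   context = "superimposed", pulses = 2L)
  expect_equal(mvc_peak(make_trace(y, events = ev)), 200)
  expect_error(mvc_peak(torque_trace(numeric(0), rate)), "empty")
})

test_that("onset detection is sample-exact on noiseless twitches", {
  sh <- control_shape()
  tw <- render_twitch(40, 30, sh, t_stim = 0.5, noise_sd = 0)
  onset <- detect_onset(tw, 0.5)
  expect_lt(abs((onset - 0.5) * 1000 - 30), 0.51)
  flat <- make_trace(rep(0, 2000))
  expect_error(detect_onset(flat, 0.5), "no-response")
  expect_error(detect_onset(tw, 0.05), "insufficient baseline")
})

test_that("onset detection stays accurate under rendering noise", {
  sh <- control_shape()
  set.seed(19)
  errs <- replicate(200, {
    tw <- render_twitch(40, 30, sh, t_stim = 0.5, noise_sd = 0.05)
    abs((detect_onset(tw, 0.5) - 0.5) * 1000 - 30)
  })
  expect_lt(mean(errs), 1.5)
})

test_that("twitch properties recover a piecewise-linear analytic pulse", {
  # symmetric triangular pulse: 50-ms rise to 10 Nm, 100-ms fall
  rate <- 2000
  t <- seq(0, 1.5, by = 1 / rate)
  stim <- 0.5
  y <- pmax(0, pmin((t - stim) / 0.05, 1 - (t - stim - 0.05) / 0.1)) * 10
  p <- twitch_properties(make_trace(y), stim)
  expect_lt(abs(p$EMD), 1.01)              # onset at the stimulus
  expect_equal(p$CT, 50, tolerance = 0.02)
  expect_equal(p$HRT, 50, tolerance = 0.03)
  expect_equal(p$P, 10, tolerance = 1e-6)
  expect_equal(p$MRTD, 0.2, tolerance = 0.01)
  expect_equal(p$MRTR, 0.1, tolerance = 0.01)
  expect_equal(p$peak_time, p$onset_time + p$CT / 1000)
})

test_that("twitch properties round-trip the rendered control twitch", {
  sh <- control_shape()
  tw <- render_twitch(77.9, 28.8, sh, t_stim = 0.5, noise_sd = 0)
  p <- twitch_properties(tw, 0.5)
  expect_equal(p$P, 77.9, tolerance = 1e-6)
  expect_lt(abs(p$EMD - 28.8), 0.51)
  expect_lt(abs(p$CT - 47.7), 1.01)
  expect_lt(abs(p$HRT - 128.2), 1.01)
  # MRTD equals the shape's own (measurement-definition) slope
  expect_equal(p$MRTD, sh$mrtd_norm * 77.9, tolerance = 0.02)
})

test_that("twitch derivative agrees with the closed-form waveform slope", {
  sh <- control_shape()
  tw <- render_twitch(77.9, 28.8, sh, t_stim = 0.5, noise_sd = 0)
  p <- twitch_properties(tw, 0.5)
  # independent computation straight from the closed-form waveform at
  # the recording resolution with the extraction's own smoothing
  tau <- seq(0, 200, by = 0.5)
  g <- 77.9 * twitch_waveform(tau, sh)
  sm <- stats::filter(g, rep(0.2, 5), sides = 2)
  oracle <- max(diff(sm, lag = 2) / 1, na.rm = TRUE)
  expect_equal(p$MRTD, oracle, tolerance = 0.02)
  # the dense analytic slope exceeds the smoothed estimate only mildly
  dense <- max(diff(77.9 * twitch_waveform(seq(0, 60, by = 0.01), sh))) / 0.01
  expect_lt(abs(p$MRTD / dense - 1), 0.15)
})

test_that("unresolved half relaxation raises an error", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  y <- ifelse(t < 0.5, 0, pmin((t - 0.5) / 0.05, 1)) * 10  # no relaxation
  expect_error(twitch_properties(make_trace(y), 0.5), "HRT")
})

test_that("doublet amplitudes use the context-specific baseline", {
  rate <- 2000
  t <- seq(0, 3, by = 1 / rate)
  sh <- control_shape()
  # superimposed on a flat 200-Nm plateau with a +12-Nm increment
  y <- rep(200, length(t))
  stim <- 1.5
  inc <- 12 * swefatigue:::evoked_component(t, stim, 28.8, sh, pulses = 2)
  p <- doublet_amplitude(make_trace(y + inc), stim, "superimposed")
  expect_equal(p, 12, tolerance = 1e-9)
  # resting doublet
  yr <- 114.3 * swefatigue:::evoked_component(t, stim, 28.8, sh, pulses = 2)
  expect_equal(doublet_amplitude(make_trace(yr), stim, "resting"), 114.3,
               tolerance = 1e-9)
  expect_error(doublet_amplitude(make_trace(yr), 0.01, "resting"),
               "insufficient baseline")
})

test_that("superimposed increment extraction is unbiased under plateau noise", {
  rate <- 2000
  t <- seq(0, 3, by = 1 / rate)
  sh <- control_shape()
  stim <- 1.5
  inc <- 12.57 * swefatigue:::evoked_component(t, stim, 28.8, sh, pulses = 2)
  set.seed(29)
  est <- replicate(200, {
    y <- 200 * (1 + rnorm(1, 0, 0.01)) + rnorm(length(t), 0, 0.05) + inc
    doublet_amplitude(make_trace(y), stim, "superimposed")
  })
  expect_lt(abs(mean(est) - 12.57), 0.5)
})

test_that("voluntary activation follows the interpolated-twitch relation", {
  expect_equal(compute_val(0, 114.3), 100)
  expect_equal(compute_val(114.3, 114.3), 0)
  expect_equal(compute_val(12.573, 114.3), 89.0)
  expect_error(compute_val(5, 0), "denominator")
  # scale invariance: common gain on both amplitudes leaves VAL unchanged
  set.seed(7)
  for (i in 1:20) {
    dbs <- runif(1, 0, 50); dbp <- runif(1, 50, 150); c0 <- runif(1, 0.1, 10)
    expect_equal(compute_val(dbs, dbp), compute_val(c0 * dbs, c0 * dbp))
  }
})

test_that("superimposed increment plus plateau never exceeds the trace max", {
  coh <- zero_noise_cohort()
  tm <- protocol_timing()
  for (s in seq_along(coh$sessions)) {
    tq <- coh$sessions[[s]][[1]]$mvc$torque
    inc <- doublet_amplitude(tq, tm$sup_doublet, "superimposed")
    base <- mean(tq$samples[swefatigue:::trace_window_idx(
      tq, tm$sup_doublet - 0.025, tm$sup_doublet)])
    expect_lte(inc + base, max(tq$samples) + 1e-9)
  }
})

test_that("supramaximal intensity is 130% of the recruitment plateau onset", {
  ints <- seq(40, 95, by = 5)
  amps <- c(1, 2.5, 4, 5.5, 6.5, 6.5, 6.5, 6.5, 6.5, 6.5, 6.5, 6.5)
  expect_equal(supramaximal_intensity(ints, amps), 1.3 * 60)
  # monotone rise never plateaus
  expect_error(supramaximal_intensity(ints, seq_along(ints)), "no-plateau")
  # sigmoid curve: result equals a direct exhaustive scan of the 2% rule
  amps2 <- 6 / (1 + exp(-(ints - 57) / 4))
  direct <- NA
  for (i in seq_along(ints)) {
    if (all(amps2[i:length(ints)] >= 0.98 * max(amps2))) { direct <- i; break }
  }
  expect_equal(supramaximal_intensity(ints, amps2), 1.3 * ints[direct])
  expect_error(supramaximal_intensity(rev(ints), amps), "increasing")
})
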