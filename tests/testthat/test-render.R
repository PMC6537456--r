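test_that("noiseless twitch renders peak torque and timing exactly", {
  sh <- control_shape()
  tw <- render_twitch(77.9, 28.8, sh, t_stim = 0.5, noise_sd = 0)
  expect_equal(max(tw$samples), 77.9)
  t <- trace_times(tw)
  peak_delay <- (t[which.max(tw$samples)] - 0.5) * 1000 - 28.8
  expect_lt(abs(peak_delay - 47.7), 0.51)   # CT within one 2-kHz sample
  expect_true(all(tw$samples[t < 0.5 + 0.0288] == 0))
})

test_that("a zero-amplitude twitch renders an all-zero trace", {
  tw <- render_twitch(0, 28.8, control_shape(), noise_sd = 0)
  expect_true(all(tw$samples == 0))
})

test_that("twitch peak extraction is unbiased under rendering noise", {
  sh <- control_shape()
  set.seed(31)
  est <- replicate(100, {
    tw <- render_twitch(77.9, 28.8, sh, t_stim = 0.5, noise_sd = 0.05)
    twitch_properties(tw, 0.5)$P
  })
  # the discrete maximum over the flat peak region carries a small
  # positive noise bias of order the noise SD
  expect_lt(abs(mean(est) - 77.9), 1.5 * 0.05)
})

test_that("stimulus placement outside the trace is rejected", {
  expect_error(render_twitch(50, 28.8, control_shape(), t_stim = 99,
                             duration = 1), "event-placement")
})

test_that("MVC trial renders the interpolated-twitch geometry", {
  cfg <- zero_noise_config()
  truth <- c(mvc = 352, val = 89, db_pot = 114.3, tw_p = 77.9, emd = 28.8,
             mmax = 5.2, rms_mmax = 0.06, vl_passive_rms = 0.004)
  trial <- render_mvc_trial(truth, control_shape(), cfg)
  tm <- protocol_timing()
  ev <- trial$events
  expect_equal(nrow(ev), 3)
  expect_equal(ev$pulses, c(2L, 2L, 1L))  # both doublets carry two pulses
  expect_equal(ev$context, c("superimposed", "resting", "resting"))
  # noiseless plateau equals the subject's MVC (to 0.1%: the peak search
  # window still sees the last traces of the relaxing increment)
  expect_equal(mvc_peak(trial$torque), 352, tolerance = 5e-4)
  # superimposed increment = Db_pot * (1 - VAL/100): 114.3 * 0.11
  inc <- doublet_amplitude(trial$torque, tm$sup_doublet, "superimposed")
  expect_equal(inc, 114.3 * 0.11, tolerance = 1e-6)
  # resting doublet renders its amplitude exactly
  dbp <- doublet_amplitude(trial$torque, tm$pot_doublet, "resting")
  expect_equal(dbp, 114.3, tolerance = 1e-9)
  # full activation leaves no superimposed increment
  truth2 <- truth; truth2["val"] <- 100
  trial2 <- render_mvc_trial(truth2, control_shape(), cfg)
  inc2 <- doublet_amplitude(trial2$torque, tm$sup_doublet, "superimposed")
  expect_equal(inc2, 0, tolerance = 1e-9)
  expect_error(render_mvc_trial(`[<-`(truth, "val", 101), control_shape(),
                                cfg), "invalid truth")
})

test_that("realized plateau tracks MVC within twice the plateau CV", {
  cfg <- sim_config(seed = 1)
  truth <- c(mvc = 352, val = 89, db_pot = 114.3, tw_p = 77.9, emd = 28.8,
             mmax = 5.2, rms_mmax = 0.06, vl_passive_rms = 0.004)
  set.seed(17)
  peaks <- replicate(20, mvc_peak(render_mvc_trial(truth, control_shape(),
                                                   cfg)$torque))
  expect_lt(abs(mean(peaks) / 352 - 1), 2 * cfg$noise$plateau_cv)
})

test_that("MVC-trial EMG carries the target RMS and M-wave amplitude", {
  cfg <- zero_noise_config()
  truth <- c(mvc = 352, val = 89, db_pot = 114.3, tw_p = 77.9, emd = 28.8,
             mmax = 5.2, rms_mmax = 0.06, vl_passive_rms = 0.004)
  set.seed(5)
  trial <- render_mvc_trial(truth, control_shape(), cfg)
  tm <- protocol_timing()
  rms <- emg_rms(trial$emg, tm$rms_window[1],
                 tm$rms_window[2] - tm$rms_window[1])
  expect_equal(rms, 0.06 * 5.2, tolerance = 1e-9)   # scaled on this window
  mm <- mwave_p2p(trial$emg, tm$pot_twitch)
  expect_equal(mm, 5.2, tolerance = 0.02)
})

test_that("noiseless elastography clip encodes the modulus exactly", {
  cfg <- zero_noise_config()
  clip <- render_swe_clip(9.3, cfg)
  expect_length(clip$frames, 5)
  expect_true(all(vapply(clip$frames, function(f)
    all(abs(f - sqrt(9.3)) < 1e-12), logical(1))))
  expect_equal(clip_modulus(clip)$clip_mu, 9.3)
  clip1 <- render_swe_clip(1, cfg)
  expect_equal(clip1$frames[[1]][1, 1], 1)
  expect_error(render_swe_clip(-2, cfg), "invalid truth")
})

test_that("within-clip frame scatter matches error propagation", {
  # d(mu)/d(Vs) = 2 Vs, so frame noise 0.045 m/s and pixel noise
  # 0.15 m/s over a 12x12 ROI give frame-mean modulus SD near 0.26 kPa
  cfg <- sim_config(seed = 1)
  set.seed(23)
  sds <- replicate(400, stats::sd(roi_frame_modulus(render_swe_clip(9.3, cfg))))
  vs <- sqrt(9.3)
  expected <- 2 * vs * sqrt(cfg$noise$frame_speed_sd^2 +
                            cfg$noise$pixel_speed_sd^2 / 144)
  expect_lt(abs(mean(sds) / expected - 1), 0.1)
  expect_lt(abs(mean(sds) - 0.26), 0.15 * 0.26)
})

test_that("scan-time passive traces encode relaxed levels", {
  cfg <- zero_noise_config()
  truth <- c(passive_torque = 0.4, vl_passive_rms = 0.004,
             bf_passive_rms = 0.002)
  set.seed(3)
  p <- render_passive(truth, cfg)
  ck <- check_relaxation(p$torque, p$vl, p$bf)
  expect_true(ck$pass)
  expect_equal(ck$torque_mean, 0.4)
  expect_equal(ck$vl_rms, 0.004, tolerance = 1e-9)
  expect_equal(ck$bf_rms, 0.002, tolerance = 1e-9)
})
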