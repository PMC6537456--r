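# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the control-condition twitch shape (group-mean contractile values)
control_shape <- function() {
  memo("control_shape",
       solve_twitch_shape(47.7, 128.2, 4.8 / 77.9, warn = FALSE))
}

# rendering noise switched off; subject variability kept
zero_noise_config <- function(n_subjects = 5, seed = 7) {
  sim_config(n_subjects = n_subjects, seed = seed,
             noise = list(plateau_cv = 0, torque_sd = 0,
                          frame_speed_sd = 0, pixel_speed_sd = 0))
}

# fully degenerate: no subject variability and no rendering noise
degenerate_config <- function(n_subjects = 2, seed = 3) {
  cal <- default_calibration()
  cal$ctrl_sd[] <- 0
  cal$end_change_sd_pct[] <- 0
  sim_config(n_subjects = n_subjects, seed = seed, calibration = cal,
             noise = list(plateau_cv = 0, torque_sd = 0,
                          frame_speed_sd = 0, pixel_speed_sd = 0))
}

# the default study cohort (15 subjects, seed 1) and its analysis
default_cohort <- function() {
  memo("default_cohort", generate_cohort(sim_config(seed = 1)))
}
default_analysis <- function() {
  memo("default_analysis", analyze_cohort(default_cohort()))
}
zero_noise_cohort <- function() {
  memo("zero_noise_cohort", generate_cohort(zero_noise_config()))
}

# long-format truth of a cohort as a quantity matrix helper
truth_matrix <- function(cohort, quantity) {
  t(vapply(cohort$truth, function(tr) tr[quantity, ],
           numeric(length(cohort$config$timepoints))))
}
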