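#' Draw one subject's ground-truth parameter trajectories
#'
#' Draws a subject baseline for every calibrated quantity and propagates it
#' through the protocol with the group-trajectory shape.  For a quantity
#' with control mean/SD (m0, s0), group trajectory m(t) and end-change
#' distribution (d, s_d) in percent, the subject value is
#'
#'   v(t) = B * (1 + dir * D * g(t)),
#'
#' where B ~ Normal(m0, s0) truncated below at 0.05 * m0, D ~
#' Normal(d, s_d)/100 is the subject's own relative end change, dir is the
#' direction of change (-1 decrease, +1 increase), and the shape
#' g(t) = (m(t)/m(1) - 1) / (m(7)/m(1) - 1) rescales the group trajectory so
#' g(Ctrl) = 0 and g(end) = 1.  Quantities flagged as non-changing use
#' D = 0 and stay at their baseline.
#'
#' Draws are independent across quantities and subjects.  A small set of
#' physiological-consistency truncations is applied after drawing (see
#' Details); they leave the calibrated distributions essentially intact but
#' prevent non-renderable or non-physical parameter combinations.
#'
#' @details Post-draw truncations:
#' * all baselines floored at 5\% of the control mean (positivity) and
#'   per-subject end changes capped at |D| <= 95\%;
#' * VAL clamped to (0, 100];
#' * HRT kept within [0.8 * CT, 340 ms] and the baseline MRTD draw raised,
#'   if necessary, to the waveform-family feasibility floor of the whole
#'   trajectory (see [twitch_slope_floor()]); raising the baseline rather
#'   than clipping single time points preserves the subject's drawn
#'   relative changes;
#' * resting (scan-time) passive torque and EMG levels capped just below
#'   the relaxation-acceptance thresholds, emulating the online monitoring
#'   that only accepts scans from relaxed subjects.
#'
#' Uses the current RNG state; seed management belongs to the caller
#' (see [generate_cohort()]).
#'
#' @param config A [sim_config()] object.
#' @param subject_index Subject number (used only for labelling).
#' @param check_feasibility Apply the MRTD waveform-feasibility band
#'   (skippable for truth-only studies of the drawing model; the draws are
#'   identical either way since the band is deterministic).
#' @return A matrix (quantity x time point) of true values with class
#'   \code{"subject_truth"}.
#' @export
draw_subject_truth <- function(config, subject_index = 1L,
                               check_feasibility = TRUE) {
  validate_config(config)
  cal <- config$calibration
  tps <- config$timepoints
  nt <- length(tps)
  v <- matrix(NA_real_, nrow = nrow(cal), ncol = nt,
              dimnames = list(cal$quantity, tps))
  for (i in seq_len(nrow(cal))) {
    m0 <- cal$ctrl_mean[i]
    B <- max(stats::rnorm(1, m0, cal$ctrl_sd[i]), 0.05 * m0)
    if (cal$changes[i]) {
      # |D| capped below 1 so trajectories keep their sign and shape
      D <- stats::rnorm(1, cal$end_change_mean_pct[i],
                        cal$end_change_sd_pct[i]) / 100
      D <- min(max(D, -0.95), 0.95)
      g <- trajectory_shape(cal$trajectory[[i]])
      v[i, ] <- B * (1 + cal$direction[i] * D * g)
    } else {
      v[i, ] <- B
    }
  }
  # positivity for all quantities at all time points
  v <- pmax(v, 0.05 * cal$ctrl_mean)
  # voluntary activation is a percentage
  v["val", ] <- pmin(pmax(v["val", ], 1), 100)
  # EMD is defined at the recording's sample resolution; snapping it to
  # the grid keeps rendered waveforms phase-aligned with their targets
  step_ms <- 1000 / config$sampling_rate
  v["emd", ] <- pmax(round(v["emd", ] / step_ms) * step_ms, step_ms)
  # twitch-shape feasibility: relaxation cannot be much faster than the
  # rise, and the rate of rise is bounded below by P/CT geometry
  v["hrt", ] <- pmin(pmax(v["hrt", ], 0.8 * v["ct", ]), 340)
  # confine the MRTD trajectory to the waveform-attainable slope band.
  # Rescaling the baseline draw (ratios intact) preserves the subject's
  # drawn relative changes -- the quantity the protocol is calibrated
  # on; only if no rescaling fits the whole trajectory are single time
  # points clamped into the band.
  if (check_feasibility) {
    mr <- v["mrtd", ]
    band <- vapply(seq_len(nt), function(ti)
      twitch_slope_band(v["ct", ti], v["hrt", ti],
                        rate = config$sampling_rate) * v["tw_p", ti],
      numeric(2))
    r <- mr / mr[1]
    lo <- max(band[1, ] / r)
    hi <- min(band[2, ] / r)
    b0 <- if (lo <= hi) min(max(mr[1], lo), hi) else sqrt(lo * hi)
    v["mrtd", ] <- pmin(pmax(b0 * r, band[1, ]), band[2, ])
  }
  # accepted scans only: relaxation monitoring caps resting activity
  v["passive_torque", ] <- pmin(v["passive_torque", ], 1.8)
  v["vl_passive_rms", ] <- pmin(v["vl_passive_rms", ], 0.009)
  v["bf_passive_rms", ] <- pmin(v["bf_passive_rms", ], 0.009)
  attr(v, "subject") <- as.integer(subject_index)
  class(v) <- c("subject_truth", class(v))
  v
}

#' Rescaled group-trajectory shape
#'
#' Maps a group-mean trajectory m(t) to the dimensionless fatigue shape
#' g(t) = (m(t)/m(1) - 1)/(m(end)/m(1) - 1), so g is 0 at control and 1 at
#' the final time point regardless of the direction of change.
#'
#' @param trajectory Numeric vector of group means, control first.
#' @return Numeric vector of the same length.
#' @export
trajectory_shape <- function(trajectory) {
  m0 <- trajectory[1]
  mend <- trajectory[length(trajectory)]
  if (m0 <= 0) stop("invalid calibration: control mean must be > 0")
  if (mend == m0) stop("invalid calibration: flat trajectory has no shape")
  (trajectory / m0 - 1) / (mend / m0 - 1)
}
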