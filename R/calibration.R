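#' Default cohort calibration table
#'
#' Group-level calibration of the synthetic fatigue cohort: one row per
#' measured quantity with its control (non-fatigued) mean and SD, the
#' group-mean trajectory over the seven protocol time points (control plus
#' after every 10 of the 60 MVCs), and the distribution of per-subject
#' relative change from control to exercise end.  Values correspond to a
#' 15-subject knee-extensor fatigue protocol of 60 repeated 5-s isometric
#' MVCs in trained young men.
#'
#' Columns:
#' \describe{
#'   \item{quantity}{identifier, see below}
#'   \item{unit}{measurement unit}
#'   \item{ctrl_mean, ctrl_sd}{between-subject distribution at control}
#'   \item{trajectory}{list column: group mean at the 7 time points}
#'   \item{end_change_mean_pct, end_change_sd_pct}{per-subject relative
#'     change from control to the 60th MVC, in percent, expressed as a
#'     magnitude in the direction given by \code{direction}}
#'   \item{direction}{-1 for quantities that decrease with fatigue, +1 for
#'     quantities that increase (EMD, CT), 0 irrelevant}
#'   \item{changes}{logical; FALSE for quantities that do not change
#'     systematically with fatigue (their per-subject trajectory is flat)}
#' }
#'
#' Quantities: \code{mvc} (MVC peak torque, Nm), \code{val} (voluntary
#' activation level, %), \code{rms_mmax} (plateau EMG RMS over M-wave
#' amplitude, a.u.), \code{db_pot} (potentiated 100-Hz doublet amplitude,
#' Nm), \code{tw_p} (potentiated twitch peak torque, Nm), \code{mmax}
#' (M-wave peak-to-peak amplitude, mV), \code{emd} (electromechanical
#' delay, ms), \code{ct} (contraction time, ms), \code{mrtd} (maximal rate
#' of torque development, Nm/ms), \code{hrt} (half relaxation time, ms),
#' \code{mrtr} (maximal rate of torque relaxation, Nm/ms), \code{mu}
#' (resting vastus lateralis shear elastic modulus, kPa),
#' \code{passive_torque} (resting knee-extensor torque during scans, Nm),
#' \code{vl_passive_rms}, \code{bf_passive_rms} (resting EMG RMS, mV).
#'
#' @return A data.frame with one row per quantity.
#' @export
default_calibration <- function() {
  tr <- function(...) list(c(...))
  cal <- data.frame(
    quantity = c("mvc", "val", "rms_mmax", "db_pot", "tw_p", "mmax",
                 "emd", "ct", "mrtd", "hrt", "mrtr", "mu",
                 "passive_torque", "vl_passive_rms", "bf_passive_rms"),
    unit = c("Nm", "%", "au", "Nm", "Nm", "mV",
             "ms", "ms", "Nm/ms", "ms", "Nm/ms", "kPa",
             "Nm", "mV", "mV"),
    ctrl_mean = c(352, 89.0, 0.06, 114.3, 77.9, 5.2,
                  28.8, 47.7, 4.8, 128.2, 4.4, 9.3,
                  0.4, 0.004, 0.002),
    ctrl_sd = c(68, 3.9, 0.02, 14.3, 10.2, 2.8,
                10.8, 9.5, 3.3, 39.7, 2.9, 2.0,
                0.1, 0.005, 0.001),
    end_change_mean_pct = c(38.4, 0, 0, 38.2, 49.4, 0,
                            21.9, 20.4, 51.0, 0, 0, 34.7,
                            0, 0, 0),
    end_change_sd_pct = c(12.6, 0, 0, 10.8, 12.6, 0,
                          6.8, 10.4, 12.7, 0, 0, 6.7,
                          0, 0, 0),
    direction = c(-1, 0, 0, -1, -1, 0,
                  +1, +1, -1, 0, 0, -1,
                  0, 0, 0),
    changes = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  cal$trajectory <- c(
    tr(352, 270, 226, 208, 202, 192, 211),            # mvc
    tr(89.0, 87.7, 82.8, 80.9, 75.9, 79.1, 81.2),     # val
    tr(0.06, 0.06, 0.06, 0.05, 0.05, 0.06, 0.07),     # rms_mmax
    tr(114.3, 94.0, 81.6, 75.0, 71.9, 73.2, 70.8),    # db_pot
    tr(77.9, 56.5, 46.7, 42.4, 41.1, 42.0, 39.6),     # tw_p
    tr(5.2, 5.2, 5.2, 5.1, 5.1, 4.8, 4.8),            # mmax
    tr(28.8, 32.0, 32.1, 33.2, 33.1, 33.9, 35.0),     # emd
    tr(47.7, 50.6, 52.2, 52.8, 54.0, 56.0, 57.5),     # ct
    tr(4.8, 3.8, 2.7, 2.4, 2.3, 2.3, 2.2),            # mrtd
    tr(128.2, 121.3, 112.6, 110.8, 110.8, 107.6, 104.8), # hrt
    tr(4.4, 3.5, 3.0, 2.7, 2.4, 2.5, 2.2),            # mrtr
    tr(9.3, 8.1, 7.5, 7.4, 6.9, 6.7, 6.1),            # mu
    tr(0.4, 0.6, 0.8, 0.6, 0.7, 0.8, 0.6),            # passive_torque
    tr(0.004, 0.004, 0.004, 0.004, 0.003, 0.003, 0.003), # vl_passive_rms
    tr(0.002, 0.002, 0.002, 0.002, 0.002, 0.002, 0.002)  # bf_passive_rms
  )
  rownames(cal) <- cal$quantity
  cal
}

#' Protocol time point labels
#'
#' @return Character vector of the seven time points: control and after
#'   every 10 of the 60 MVCs.
#' @export
timepoint_labels <- function() {
  c("Ctrl", "MVC10", "MVC20", "MVC30", "MVC40", "MVC50", "MVC60")
}

#' Synthetic cohort generator configuration
#'
#' Assembles and validates the configuration of the synthetic experiment
#' generator.  Defaults reproduce the study conditions: 15 subjects, seven
#' time points, 2-kHz torque/EMG sampling, 40 x 40 shear-wave-speed maps at
#' 1 mm/pixel with a 12 x 12 pixel ROI (~1.44 cm^2), and rendering noise at
#' physiological scales.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sampling_rate Torque/EMG sampling rate in Hz.
#' @param map_shape Integer vector (rows, cols) of the speed map in pixels
#'   (1 x 1 mm pixels).
#' @param roi_side Side of the square ROI in pixels; must fit in the map.
#' @param frame_interval Time between elastography frames in seconds.
#' @param n_frames Frames per elastography clip.
#' @param noise List of rendering noise parameters:
#'   \code{plateau_cv} (CV of the realized MVC plateau level),
#'   \code{torque_sd} (additive torque noise SD, Nm),
#'   \code{frame_speed_sd} (per-frame shear-wave speed offset SD, m/s),
#'   \code{pixel_speed_sd} (per-pixel speed noise SD, m/s).
#'   Omitted entries keep their defaults.
#' @param calibration Calibration table, see [default_calibration()].
#' @param seed Integer seed stored with the config; [generate_cohort()]
#'   sets it before drawing.
#'
#' @return A list of class \code{"swe_config"}.
#' @export
sim_config <- function(n_subjects = 15,
                       sampling_rate = 2000,
                       map_shape = c(40L, 40L),
                       roi_side = 12L,
                       frame_interval = 1,
                       n_frames = 5L,
                       noise = list(),
                       calibration = default_calibration(),
                       seed = 1L) {
  default_noise <- list(
    plateau_cv = 0.01,
    torque_sd = 0.05,
    frame_speed_sd = 0.045,
    pixel_speed_sd = 0.15
  )
  noise <- utils::modifyList(default_noise, noise)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    timepoints = timepoint_labels(),
    sampling_rate = sampling_rate,
    map_shape = as.integer(map_shape),
    roi_side = as.integer(roi_side),
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    noise = noise,
    calibration = calibration,
    seed = as.integer(seed)
  )
  class(cfg) <- "swe_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "swe_config"))
  if (cfg$n_subjects < 2)
    stop("invalid calibration: n_subjects must be >= 2")
  cal <- cfg$calibration
  if (any(lengths(cal$trajectory) != length(cfg$timepoints)))
    stop("invalid calibration: trajectories must have one entry per time point")
  if (any(cal$ctrl_sd < 0))
    stop("invalid calibration: ctrl_sd must be >= 0")
  if (any(cal$ctrl_mean <= 0))
    stop("invalid calibration: ctrl_mean must be > 0")
  if (cfg$roi_side > min(cfg$map_shape))
    stop("invalid calibration: ROI does not fit inside the map")
  if (cfg$sampling_rate <= 0)
    stop("invalid calibration: sampling_rate must be > 0")
  invisible(cfg)
}

#' @export
print.swe_config <- function(x, ...) {
  cat("Synthetic fatigue cohort configuration\n")
  cat(sprintf("  subjects: %d, time points: %s\n", x$n_subjects,
              paste(x$timepoints, collapse = " ")))
  cat(sprintf("  sampling rate: %g Hz; map %d x %d px, ROI %d px; %d frames @ %g s\n",
              x$sampling_rate, x$map_shape[1], x$map_shape[2],
              x$roi_side, x$n_frames, x$frame_interval))
  cat(sprintf("  noise: plateau_cv=%g, torque_sd=%g Nm, frame=%g m/s, pixel=%g m/s\n",
              x$noise$plateau_cv, x$noise$torque_sd,
              x$noise$frame_speed_sd, x$noise$pixel_speed_sd))
  invisible(x)
}

#' Write / read a generator configuration as a flat key-value file
#'
#' The calibration table is flattened to per-quantity keys so the whole
#' configuration round-trips through a plain text file.
#'
#' @param cfg A \code{swe_config}.
#' @param path File path.
#' @return \code{read_config} returns a \code{swe_config}.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  cal <- cfg$calibration
  flat <- list(
    n_subjects = cfg$n_subjects,
    sampling_rate = cfg$sampling_rate,
    map_shape = cfg$map_shape,
    roi_side = cfg$roi_side,
    frame_interval = cfg$frame_interval,
    n_frames = cfg$n_frames,
    noise = cfg$noise,
    seed = cfg$seed,
    quantities = lapply(seq_len(nrow(cal)), function(i) {
      list(quantity = cal$quantity[i], unit = cal$unit[i],
           ctrl_mean = cal$ctrl_mean[i], ctrl_sd = cal$ctrl_sd[i],
           trajectory = cal$trajectory[[i]],
           end_change_mean_pct = cal$end_change_mean_pct[i],
           end_change_sd_pct = cal$end_change_sd_pct[i],
           direction = cal$direction[i], changes = cal$changes[i])
    })
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  cal <- do.call(rbind, lapply(flat$quantities, function(q) {
    data.frame(quantity = q$quantity, unit = q$unit,
               ctrl_mean = q$ctrl_mean, ctrl_sd = q$ctrl_sd,
               end_change_mean_pct = q$end_change_mean_pct,
               end_change_sd_pct = q$end_change_sd_pct,
               direction = q$direction, changes = q$changes,
               stringsAsFactors = FALSE)
  }))
  cal$trajectory <- lapply(flat$quantities, function(q) as.numeric(q$trajectory))
  rownames(cal) <- cal$quantity
  sim_config(n_subjects = flat$n_subjects,
             sampling_rate = flat$sampling_rate,
             map_shape = flat$map_shape,
             roi_side = flat$roi_side,
             frame_interval = flat$frame_interval,
             n_frames = flat$n_frames,
             noise = flat$noise,
             calibration = cal,
             seed = flat$seed)
}
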