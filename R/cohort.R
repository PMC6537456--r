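#' Generate a full synthetic fatigue cohort
#'
#' Draws ground-truth parameter trajectories for every subject
#' ([draw_subject_truth()]), solves each subject/time-point twitch shape
#' ([solve_twitch_shape()]) and renders the complete measurement set of
#' every protocol time point: the MVC trial with its superimposed and
#' resting stimulations and EMG ([render_mvc_trial()]), the resting
#' elastography clip ([render_swe_clip()]) and the scan-time relaxation
#' monitoring traces ([render_passive()]).
#'
#' The configured seed makes the dataset fully reproducible: identical
#' configuration and seed give identical output.  Ground truth is stored
#' alongside the rendered signals for recovery testing; the achieved
#' (rendered) MRTD is recorded separately because slope targets below the
#' waveform family's floor are rendered best-effort.
#'
#' @param config A [sim_config()].
#' @return An object of class \code{"swe_cohort"}: list with
#'   \code{config}, \code{truth} (list of subject-truth matrices),
#'   \code{sessions} (\code{sessions[[subject]][[timepoint]]}, each with
#'   \code{mvc}, \code{clip}, \code{passive}, \code{shape}) and
#'   \code{achieved} (data.frame of rendered twitch-shape metrics per
#'   cell).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  tps <- config$timepoints
  truth <- lapply(seq_len(n), function(s) draw_subject_truth(config, s))
  sessions <- vector("list", n)
  achieved <- vector("list", n * length(tps))
  for (s in seq_len(n)) {
    sessions[[s]] <- stats::setNames(vector("list", length(tps)), tps)
    for (ti in seq_along(tps)) {
      tr <- truth[[s]][, ti]
      shape <- solve_twitch_shape(tr[["ct"]], tr[["hrt"]],
                                  tr[["mrtd"]] / tr[["tw_p"]],
                                  rate = config$sampling_rate, warn = FALSE)
      sessions[[s]][[ti]] <- list(
        mvc = render_mvc_trial(tr, shape, config),
        clip = render_swe_clip(tr[["mu"]], config),
        passive = render_passive(tr, config),
        shape = shape
      )
      achieved[[(s - 1) * length(tps) + ti]] <- data.frame(
        subject = s, timepoint = tps[ti],
        mrtd_norm_target = tr[["mrtd"]] / tr[["tw_p"]],
        mrtd_norm_achieved = shape$mrtd_norm,
        mrtd_achieved = shape$mrtd_norm * tr[["tw_p"]],
        feasible = shape$feasible,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(config = config, truth = truth, sessions = sessions,
                 achieved = do.call(rbind, achieved)),
            class = "swe_cohort")
}

#' @export
print.swe_cohort <- function(x, ...) {
  cat(sprintf("synthetic fatigue cohort: %d subjects x %d time points (seed %d)\n",
              x$config$n_subjects, length(x$config$timepoints),
              x$config$seed))
  invisible(x)
}

#' Ground truth of a cohort as a long table
#'
#' @param cohort An \code{"swe_cohort"}.
#' @return data.frame with columns subject, timepoint, quantity, value.
#' @export
truth_table <- function(cohort) {
  tps <- cohort$config$timepoints
  out <- lapply(seq_along(cohort$truth), function(s) {
    tr <- cohort$truth[[s]]
    data.frame(subject = s,
               timepoint = rep(tps, each = nrow(tr)),
               quantity = rep(rownames(tr), length(tps)),
               value = as.vector(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a rendered cohort as plain delimited text
#'
#' Lays the dataset out as one directory per subject with one
#' sub-directory per time point: traces as two-column tab-separated files
#' (\code{time_s}, value), speed maps as one plain numeric matrix file
#' per frame (m/s), events and truth as delimited tables with a header
#' row, the configuration as a key-value file, and a clip manifest giving
#' each frame file, its timestamp and the ROI (row0, col0, height, width;
#' 0-based, half-open).
#'
#' @param cohort An \code{"swe_cohort"}.
#' @param dir Output directory (created if needed).
#' @return \code{read_cohort} returns an \code{"swe_cohort"} (without the
#'   solved shape objects, which belong to generation).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cohort$config, file.path(dir, "config.yaml"))
  fw <- function(d, path) data.table::fwrite(d, path, sep = "\t")
  fw(cohort$achieved, file.path(dir, "achieved_shapes.tsv"))
  tps <- cohort$config$timepoints
  for (s in seq_along(cohort$sessions)) {
    sdir <- file.path(dir, sprintf("subject%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    tr <- cohort$truth[[s]]
    fw(data.frame(quantity = rep(rownames(tr), ncol(tr)),
                  timepoint = rep(colnames(tr), each = nrow(tr)),
                  value = as.vector(tr)),
       file.path(sdir, "truth.tsv"))
    for (ti in seq_along(tps)) {
      tdir <- file.path(sdir, tps[ti])
      dir.create(tdir, showWarnings = FALSE)
      ses <- cohort$sessions[[s]][[ti]]
      wtr <- function(trace, name, col) {
        fw(stats::setNames(data.frame(trace_times(trace), trace$samples),
                           c("time_s", col)),
           file.path(tdir, name))
      }
      wtr(ses$mvc$torque, "trial_torque.tsv", "torque_nm")
      wtr(ses$mvc$emg, "trial_emg.tsv", "emg_mv")
      wtr(ses$passive$torque, "passive_torque.tsv", "torque_nm")
      wtr(ses$passive$vl, "passive_emg_vl.tsv", "emg_mv")
      wtr(ses$passive$bf, "passive_emg_bf.tsv", "emg_mv")
      fw(ses$mvc$events, file.path(tdir, "events.tsv"))
      frame_files <- sprintf("swe_frame_%d.tsv", seq_along(ses$clip$frames))
      for (k in seq_along(ses$clip$frames))
        data.table::fwrite(as.data.frame(ses$clip$frames[[k]]),
                           file.path(tdir, frame_files[k]),
                           sep = "\t", col.names = FALSE)
      fw(data.frame(frame_file = frame_files,
                    timestamp_s = (seq_along(frame_files) - 1) *
                      ses$clip$frame_interval,
                    roi_row0 = ses$clip$roi[1], roi_col0 = ses$clip$roi[2],
                    roi_height = ses$clip$roi[3], roi_width = ses$clip$roi[4]),
         file.path(tdir, "clip_manifest.tsv"))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  config <- read_config(file.path(dir, "config.yaml"))
  fr <- function(path) as.data.frame(data.table::fread(path, sep = "\t"))
  achieved <- fr(file.path(dir, "achieved_shapes.tsv"))
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  sdirs <- sdirs[grepl("subject[0-9]+$", sdirs)]
  tps <- config$timepoints
  truth <- list(); sessions <- list()
  for (s in seq_along(sdirs)) {
    tt <- fr(file.path(sdirs[s], "truth.tsv"))
    tm <- matrix(tt$value, nrow = length(unique(tt$quantity)),
                 dimnames = list(unique(tt$quantity), tps))
    truth[[s]] <- tm
    sessions[[s]] <- stats::setNames(vector("list", length(tps)), tps)
    for (ti in seq_along(tps)) {
      tdir <- file.path(sdirs[s], tps[ti])
      events <- fr(file.path(tdir, "events.tsv"))
      rtr <- function(name, maker, ...) {
        d <- fr(file.path(tdir, name))
        maker(d[[2]], rate = config$sampling_rate, t0 = d$time_s[1], ...)
      }
      man <- fr(file.path(tdir, "clip_manifest.tsv"))
      frames <- lapply(man$frame_file, function(f)
        as.matrix(data.table::fread(file.path(tdir, f), sep = "\t",
                                    header = FALSE)))
      frames <- lapply(frames, unname)
      clip <- swe_clip(frames, pixel_mm = 1,
                       frame_interval = config$frame_interval,
                       roi = c(man$roi_row0[1], man$roi_col0[1],
                               man$roi_height[1], man$roi_width[1]))
      d <- fr(file.path(tdir, "trial_torque.tsv"))
      tq <- torque_trace(d[[2]], config$sampling_rate, t0 = d$time_s[1],
                         events = events)
      d <- fr(file.path(tdir, "trial_emg.tsv"))
      em <- emg_trace(d[[2]], config$sampling_rate, t0 = d$time_s[1],
                      events = events, channel = "VL")
      sessions[[s]][[ti]] <- list(
        mvc = list(torque = tq, emg = em, events = events),
        clip = clip,
        passive = list(torque = rtr("passive_torque.tsv", torque_trace),
                       vl = rtr("passive_emg_vl.tsv", emg_trace,
                                channel = "VL"),
                       bf = rtr("passive_emg_bf.tsv", emg_trace,
                                channel = "BF")),
        shape = NULL)
    }
  }
  structure(list(config = config, truth = truth, sessions = sessions,
                 achieved = achieved),
            class = "swe_cohort")
}
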