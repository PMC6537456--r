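#' Extract all fatigue metrics from one rendered session
#'
#' Runs the full extraction battery on one subject/time-point measurement
#' set: MVC peak with the stimulus guard, superimposed and potentiated
#' doublet amplitudes and the voluntary activation level, the six twitch
#' contractile properties from the potentiated single twitch, plateau EMG
#' RMS and its M-wave normalization (the M-wave is read at the resting
#' potentiated single twitch), the clip-averaged shear modulus, the
#' scan-time passive levels and the relaxation check.
#'
#' @param session One element of \code{cohort$sessions[[s]]}: list with
#'   \code{mvc} (torque + EMG + events), \code{clip}, \code{passive}.
#' @return Named list: numeric metrics plus \code{relax_pass}.
#' @export
extract_session_metrics <- function(session) {
  tq <- session$mvc$torque
  em <- session$mvc$emg
  ev <- tq$events
  t_sup <- ev$time[ev$context == "superimposed"][1]
  t_dbl <- ev$time[ev$context == "resting" & ev$kind == "doublet100Hz"][1]
  t_tw <- ev$time[ev$context == "resting" & ev$kind == "single"][1]

  mvc <- mvc_peak(tq)
  db_s <- doublet_amplitude(tq, t_sup, "superimposed")
  db_p <- doublet_amplitude(tq, t_dbl, "resting")
  val <- compute_val(max(db_s, 0), db_p)
  tw <- twitch_properties(tq, t_tw)

  rms_win <- protocol_timing()$rms_window
  rms <- emg_rms(em, rms_win[1], rms_win[2] - rms_win[1])
  mmax <- mwave_p2p(em, t_tw)
  relax <- check_relaxation(session$passive$torque, session$passive$vl,
                            session$passive$bf)
  mu <- clip_modulus(session$clip)$clip_mu

  list(mvc = mvc, db_sup = db_s, db_pot = db_p, val = val,
       tw_p = tw$P, emd = tw$EMD, ct = tw$CT, hrt = tw$HRT,
       mrtd = tw$MRTD, mrtr = tw$MRTR,
       rms = rms, mmax = mmax, rms_mmax = normalized_rms(rms, mmax),
       mu = mu,
       passive_torque = relax$torque_mean,
       vl_passive_rms = relax$vl_rms, bf_passive_rms = relax$bf_rms,
       relax_pass = relax$pass)
}

#' Analyze a cohort dataset end to end
#'
#' Extracts every metric from every rendered session, assembles
#' per-subject time-courses, and computes the cohort summary: per-quantity
#' means and SDs at each time point, mean and SD of the per-subject
#' relative changes from control, the one-way repeated-measures ANOVA
#' over time, and Fisher LSD contrasts of each time point against
#' control (gated on the omnibus test).  Elastography cells whose
#' relaxation check fails are flagged and excluded; a quantity with an
#' incomplete subject grid is dropped from the ANOVA.
#'
#' @param cohort An \code{"swe_cohort"} from [generate_cohort()] or
#'   [read_cohort()], or a directory path of a written cohort.
#' @param lsd_alpha Omnibus gate for the LSD contrasts.
#' @return An object of class \code{"cohort_summary"}: list with
#'   \code{metrics} (long per-cell table), \code{summary} (mean/SD per
#'   quantity x time point), \code{changes} (mean/SD of per-subject
#'   percent changes), \code{anova}, \code{lsd}, \code{excluded}.
#' @export
analyze_cohort <- function(cohort, lsd_alpha = 0.05) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "swe_cohort"))
  tps <- cohort$config$timepoints
  n <- length(cohort$sessions)

  rows <- list(); excluded <- list()
  for (s in seq_len(n)) {
    for (ti in seq_along(tps)) {
      met <- extract_session_metrics(cohort$sessions[[s]][[ti]])
      if (!met$relax_pass) {
        excluded[[length(excluded) + 1]] <- data.frame(
          subject = s, timepoint = tps[ti],
          reason = "relaxation check failed", stringsAsFactors = FALSE)
        met$mu <- NA_real_
      }
      met$relax_pass <- NULL
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, timepoint = tps[ti],
        quantity = names(met), value = unlist(met),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  metrics <- do.call(rbind, rows)
  metrics$timepoint <- factor(metrics$timepoint, levels = tps)

  quantities <- unique(metrics$quantity)
  summ <- list(); chg <- list(); anova <- list(); lsd <- list()
  for (q in quantities) {
    m <- metrics_matrix(metrics, q, tps)
    mu_t <- apply(m, 2, mean, na.rm = TRUE)
    sd_t <- apply(m, 2, stats::sd, na.rm = TRUE)
    summ[[q]] <- data.frame(quantity = q, timepoint = tps, mean = mu_t,
                            sd = sd_t, n = colSums(!is.na(m)),
                            row.names = NULL, stringsAsFactors = FALSE)
    rc <- t(apply(m, 1, relative_change))
    chg[[q]] <- data.frame(quantity = q, timepoint = tps,
                           change_mean_pct = colMeans(rc, na.rm = TRUE),
                           change_sd_pct = apply(rc, 2, stats::sd,
                                                 na.rm = TRUE),
                           row.names = NULL, stringsAsFactors = FALSE)
    complete <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(complete) >= 2) {
      an <- rm_anova_oneway(complete)
      anova[[q]] <- data.frame(quantity = q, F = an$F, df1 = an$df1,
                               df2 = an$df2, p = an$p,
                               stringsAsFactors = FALSE)
      ls <- fisher_lsd(complete, alpha = lsd_alpha, anova = an)
      ls$quantity <- q
      ls$timepoint <- tps[ls$timepoint]
      lsd[[q]] <- ls
    }
  }
  structure(list(metrics = metrics,
                 summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 changes = do.call(rbind, c(chg, make.row.names = FALSE)),
                 anova = do.call(rbind, c(anova, make.row.names = FALSE)),
                 lsd = do.call(rbind, c(lsd, make.row.names = FALSE)),
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                 else NULL,
                 timepoints = tps),
            class = "cohort_summary")
}

#' Subjects x time points matrix of one quantity
#'
#' @param metrics Long metrics table (subject, timepoint, quantity, value).
#' @param quantity Quantity name.
#' @param timepoints Time point levels (column order).
#' @return Numeric matrix, subjects in rows.
#' @export
metrics_matrix <- function(metrics, quantity,
                           timepoints = levels(metrics$timepoint)) {
  d <- metrics[metrics$quantity == quantity, ]
  subjects <- sort(unique(d$subject))
  m <- matrix(NA_real_, length(subjects), length(timepoints),
              dimnames = list(subjects, timepoints))
  m[cbind(match(d$subject, subjects), match(as.character(d$timepoint),
                                            timepoints))] <- d$value
  m
}

#' @export
print.cohort_summary <- function(x, ...) {
  n <- length(unique(x$metrics$subject))
  cat(sprintf("cohort summary: %d subjects, %d time points\n",
              n, length(x$timepoints)))
  key <- c("mvc", "db_pot", "tw_p", "mu", "emd", "ct", "mrtd")
  end <- x$timepoints[length(x$timepoints)]
  for (q in intersect(key, unique(x$changes$quantity))) {
    ch <- x$changes[x$changes$quantity == q & x$changes$timepoint == end, ]
    an <- x$anova[x$anova$quantity == q, ]
    cat(sprintf("  %-7s end change %+6.1f +/- %4.1f %%   F(%d,%d)=%.1f, p=%.2g\n",
                q, ch$change_mean_pct, ch$change_sd_pct,
                an$df1, an$df2, an$F, an$p))
  }
  if (!is.null(x$excluded))
    cat(sprintf("  excluded cells: %d (relaxation)\n", nrow(x$excluded)))
  invisible(x)
}
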