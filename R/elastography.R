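#' Shear elastic modulus from shear-wave speed
#'
#' mu = rho * Vs^2, with rho the muscle density (1000 kg/m^3) and Vs the
#' shear-wave speed in m/s; reported in kPa.  This is the shear modulus
#' (no factor of 3 -- not Young's modulus).
#'
#' @param vs Shear-wave speed, m/s (>= 0); vectorized.
#' @param density Tissue density, kg/m^3.
#' @return Shear elastic modulus, kPa.
#' @export
mu_from_speed <- function(vs, density = 1000) {
  if (any(vs < 0)) stop("invalid-speed error: shear-wave speed must be >= 0")
  density * vs^2 / 1000
}

#' Per-frame ROI-mean shear modulus of a clip
#'
#' Converts each ROI pixel of each frame to modulus (kPa) and averages
#' within the ROI.  Conversion is pixel-wise before averaging: averaging
#' speeds first and then squaring would bias the modulus low by the
#' within-ROI speed variance.
#'
#' @param clip An [swe_clip()].
#' @param density Tissue density, kg/m^3.
#' @return Numeric vector of per-frame ROI-mean moduli, kPa.
#' @export
roi_frame_modulus <- function(clip, density = 1000) {
  r <- clip$roi
  rows <- (r[1] + 1):(r[1] + r[3])
  cols <- (r[2] + 1):(r[2] + r[4])
  vapply(clip$frames,
         function(f) mean(mu_from_speed(f[rows, cols], density)),
         numeric(1))
}

#' Clip-average shear modulus
#'
#' Mean of the per-frame ROI-mean moduli over the clip; the protocol
#' records five frames at 1 Hz, so a different frame count triggers a
#' warning.
#'
#' @param clip An [swe_clip()].
#' @param density Tissue density, kg/m^3.
#' @param expected_frames Protocol frame count.
#' @return List of class \code{"modulus_result"}: \code{per_frame_mu}
#'   (kPa), \code{clip_mu} (kPa), \code{density}.
#' @export
clip_modulus <- function(clip, density = 1000, expected_frames = 5) {
  per <- roi_frame_modulus(clip, density)
  if (length(per) != expected_frames)
    warning(sprintf("clip has %d frame(s); protocol expects %d",
                    length(per), expected_frames))
  structure(list(per_frame_mu = per, clip_mu = mean(per), density = density),
            class = "modulus_result")
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("clip modulus: %.2f kPa (frames: %s)\n", x$clip_mu,
              paste(sprintf("%.2f", x$per_frame_mu), collapse = ", ")))
  invisible(x)
}

#' Intraclass correlation coefficient and standard error of measurement
#'
#' Two-way consistency, single-measure formulation from the balanced
#' subjects x measures ANOVA decomposition:
#' ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error) and
#' SEM = sqrt(MS_error) (the typical error), where MS_error is the
#' residual mean square after removing subject and measure effects.
#'
#' @param m Numeric matrix, subjects in rows, repeated measures in
#'   columns; no missing cells.
#' @return List of class \code{"reliability_result"}: \code{icc}
#'   (fraction), \code{sem} (input units), \code{n_subjects},
#'   \code{n_measures}, \code{ms_subjects}, \code{ms_error}.
#' @export
icc_sem <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("insufficient data: need >= 2 subjects and >= 2 measures")
  if (anyNA(m)) stop("insufficient data: missing cells")
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_meas <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_meas
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- if (ms_subj + (k - 1) * ms_err == 0) NA_real_ else
    (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
  structure(list(icc = icc, sem = sqrt(max(ms_err, 0)),
                 n_subjects = n, n_measures = k,
                 ms_subjects = ms_subj, ms_error = ms_err),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f, SEM = %.4g (%d subjects x %d measures)\n",
              x$icc, x$sem, x$n_subjects, x$n_measures))
  invisible(x)
}
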