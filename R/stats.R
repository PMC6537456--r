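#' Relative change from the control time point
#'
#' 100 * (v_t - v_ctrl) / v_ctrl per time point.  Cohort-level relative
#' changes are the mean over subjects of these per-subject changes
#' (mean of ratios), not the change of the group means.
#'
#' @param values Numeric vector over time points.
#' @param control_index Index of the control value.
#' @return Percent change per time point (0 at control).
#' @export
relative_change <- function(values, control_index = 1) {
  v0 <- values[control_index]
  if (is.na(v0) || v0 == 0)
    stop("invalid control: control value must be nonzero")
  100 * (values - v0) / v0
}

#' One-way repeated-measures ANOVA
#'
#' Balanced subjects x time decomposition
#' SS_total = SS_subjects + SS_time + SS_error with
#' F = MS_time / MS_error, df1 = m - 1, df2 = (n - 1)(m - 1), and the
#' p-value from the central F distribution.  No sphericity correction is
#' applied.  When MS_error is exactly zero and a time effect exists the
#' degenerate result is reported as F = Inf with p = 0.
#'
#' @param m Numeric matrix, subjects in rows, time points in columns,
#'   complete (no missing cells).
#' @return List of class \code{"rm_anova"}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}, plus \code{ms_time}, \code{ms_error},
#'   \code{n_subjects}, \code{means} (column means).
#' @export
rm_anova_oneway <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("incomplete design: need >= 2 subjects and >= 2 time points")
  if (anyNA(m)) stop("incomplete design: missing cells")
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_subj - ss_time
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_time <- ss_time / df1
  ms_err <- max(ss_err, 0) / df2
  if (ms_err == 0) {
    F <- if (ms_time > 0) Inf else 0
    p <- if (ms_time > 0) 0 else 1
  } else {
    F <- ms_time / ms_err
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = F, df1 = df1, df2 = df2, p = p,
                 ms_time = ms_time, ms_error = ms_err,
                 n_subjects = n, means = colMeans(m)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Fisher's LSD post hoc test versus control
#'
#' Pairwise t-tests of each time point against the reference using the
#' ANOVA error term: t = (mean_t - mean_ref) / sqrt(2 MS_error / n) on
#' df2 degrees of freedom, two-sided, with no multiplicity adjustment.
#' Applied only when the omnibus RM-ANOVA is significant; otherwise the
#' contrasts are marked untested.
#'
#' @param m Subjects x time points matrix.
#' @param reference_index Column of the control time point.
#' @param alpha Omnibus significance gate.
#' @param anova Optional precomputed [rm_anova_oneway()] result for `m`.
#' @return data.frame with one row per non-reference time point:
#'   \code{timepoint} (column index), \code{diff}, \code{t}, \code{p},
#'   \code{tested}.
#' @export
fisher_lsd <- function(m, reference_index = 1, alpha = 0.05, anova = NULL) {
  m <- as.matrix(m)
  if (is.null(anova)) anova <- rm_anova_oneway(m)
  n <- nrow(m)
  mu <- colMeans(m)
  idx <- setdiff(seq_len(ncol(m)), reference_index)
  diffs <- mu[idx] - mu[reference_index]
  tested <- is.finite(anova$p) && anova$p < alpha
  if (!tested) {
    return(data.frame(timepoint = idx, diff = diffs, t = NA_real_,
                      p = NA_real_, tested = FALSE, row.names = NULL))
  }
  se <- sqrt(2 * anova$ms_error / n)
  if (se == 0) {
    tt <- ifelse(diffs == 0, 0, sign(diffs) * Inf)
    pp <- ifelse(diffs == 0, 1, 0)
  } else {
    tt <- diffs / se
    pp <- 2 * stats::pt(abs(tt), anova$df2, lower.tail = FALSE)
  }
  data.frame(timepoint = idx, diff = diffs, t = tt, p = pp, tested = TRUE,
             row.names = NULL)
}

#' Power of the repeated-measures within-factor F test
#'
#' Power of the omnibus within-subject effect for n subjects and m
#' repeated measures at effect size f (Cohen), mean inter-measure
#' correlation \code{corr} and nonsphericity \code{epsilon}:
#' noncentrality lambda = f^2 n m / (1 - corr) * epsilon,
#' df1 = (m - 1) epsilon, df2 = (n - 1)(m - 1) epsilon, and
#' power = P(F'(df1, df2, lambda) > F_crit(alpha)).
#'
#' @param n Subjects.
#' @param f Cohen's effect size f (> 0).
#' @param m Number of repeated measures (>= 2).
#' @param corr Mean correlation among repeated measures.
#' @param alpha Significance level.
#' @param epsilon Nonsphericity correction in (0, 1].
#' @return Power in (0, 1).
#' @export
rm_anova_power <- function(n, f, m, corr = 0.5, alpha = 0.05, epsilon = 1) {
  lambda <- f^2 * n * m / (1 - corr) * epsilon
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size for the repeated-measures within-factor test
#'
#' Smallest n whose within-factor power (see [rm_anova_power()]) reaches
#' the target.
#'
#' @param f Cohen's effect size f (> 0).
#' @param alpha Significance level in (0, 1).
#' @param target_power Target power in (0, 1).
#' @param m Number of repeated measures (>= 2).
#' @param corr Mean correlation among repeated measures.
#' @param epsilon Nonsphericity correction in (0, 1].
#' @param n_max Search bound.
#' @return Minimal number of subjects.
#' @export
rm_power_sample_size <- function(f, alpha = 0.05, target_power = 0.95,
                                 m = 7, corr = 0.5, epsilon = 1,
                                 n_max = 10000) {
  stopifnot(f > 0, alpha > 0, alpha < 1, target_power > 0,
            target_power < 1, m >= 2, corr < 1, epsilon > 0, epsilon <= 1)
  for (n in 2:n_max) {
    if (rm_anova_power(n, f, m, corr, alpha, epsilon) >= target_power)
      return(n)
  }
  stop("non-convergence: no n <= n_max reaches the target power")
}
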