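test_that("relative change is anchored at control", {
  expect_equal(relative_change(c(10, 5)), c(0, -50))
  expect_equal(relative_change(rep(7, 5)), rep(0, 5))
  # ratio of Table-style group means differs by design from the
  # mean-of-ratios cohort statistic
  expect_equal(relative_change(c(9.3, 6.1))[2], -34.41, tolerance = 1e-3)
  expect_error(relative_change(c(0, 5)), "invalid control")
})

test_that("RM-ANOVA handles degenerate designs with exact sums", {
  # every subject constant over time
  m_const <- matrix(rep(c(3, 5, 9, 11), times = 3), 4, 3)
  a <- rm_anova_oneway(m_const)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # zero-error design with a time effect: F reported as Inf sentinel
  m <- matrix(c(10, 9, 8, 12, 11, 10, 14, 13, 12), 3, 3, byrow = TRUE)
  a2 <- rm_anova_oneway(m)
  expect_equal(a2$ms_time * a2$df1, 6)   # SS_time = 6
  expect_equal(a2$ms_error, 0)
  expect_true(is.infinite(a2$F))
  expect_equal(a2$p, 0)
  expect_error(rm_anova_oneway(matrix(1:3, 1)), "incomplete")
  expect_error(rm_anova_oneway(matrix(c(1, 2, NA, 4), 2)), "incomplete")
})

test_that("RM-ANOVA equals the aov error-stratum decomposition", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rnorm(4 * 3, mean = rep(c(0, 1, 2), each = 4)), 4, 3)
    a <- rm_anova_oneway(m)
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(1:4, 3)),
                    time = factor(rep(1:3, each = 4)))
    s <- summary(stats::aov(y ~ time + Error(subj), data = d))
    tab <- s[["Error: Within"]][[1]]
    expect_equal(a$F, tab["time", "F value"], tolerance = 1e-10)
    expect_equal(a$p, tab["time", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(a$df1, tab["time", "Df"])
    expect_equal(a$df2, tab["Residuals", "Df"])
  }
})

test_that("RM-ANOVA is invariant to subject and global offsets", {
  set.seed(33)
  m <- matrix(rnorm(6 * 4), 6, 4)
  a <- rm_anova_oneway(m)
  a_subj <- rm_anova_oneway(m + rnorm(6) %o% rep(1, 4) * 10)
  a_glob <- rm_anova_oneway(m + 42)
  expect_equal(a_subj$F, a$F)
  expect_equal(a_glob$F, a$F)
})

test_that("null p-values are uniform", {
  set.seed(55)
  ps <- replicate(2000, rm_anova_oneway(matrix(rnorm(8 * 4), 8, 4))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Fisher LSD matches a hand-built contrast on the error term", {
  set.seed(8)
  m <- matrix(rnorm(5 * 3, mean = rep(c(0, 0.5, 2), each = 5)), 5, 3)
  a <- rm_anova_oneway(m)
  ls <- fisher_lsd(m, anova = a)
  # independent construction of the same contrasts
  for (k in 1:2) {
    d <- mean(m[, k + 1]) - mean(m[, 1])
    tt <- d / sqrt(2 * a$ms_error / 5)
    expect_equal(ls$t[k], tt)
    expect_equal(ls$p[k], 2 * stats::pt(-abs(tt), a$df2))
  }
  # equal column means give t = 0, p = 1 (testing forced on)
  m0 <- matrix(rnorm(6 * 3), 6, 3)
  m0 <- sweep(m0, 2, colMeans(m0))   # exactly equal (zero) means
  ls0 <- fisher_lsd(m0, alpha = 2)
  expect_equal(ls0$t, c(0, 0))
  expect_equal(ls0$p, c(1, 1))
})

test_that("LSD is gated on the omnibus test", {
  set.seed(66)
  m <- matrix(rnorm(6 * 4), 6, 4)   # null: omnibus almost surely ns
  a <- rm_anova_oneway(m)
  if (a$p >= 0.05) {
    ls <- fisher_lsd(m, anova = a)
    expect_true(all(!ls$tested))
    expect_true(all(is.na(ls$p)))
  }
  # strong effect: gate opens
  m2 <- m + rep(c(0, 0, 0, 5), each = 6)
  ls2 <- fisher_lsd(m2)
  expect_true(all(ls2$tested))
})

test_that("sample-size search reproduces the planned cohort", {
  expect_identical(rm_power_sample_size(f = 0.40, alpha = 0.05,
                                        target_power = 0.95, m = 7,
                                        corr = 0.5, epsilon = 1), 11L)
})

test_that("power and sample size move the right way with the inputs", {
  n1 <- rm_power_sample_size(0.40, m = 7)
  expect_lte(rm_power_sample_size(0.80, m = 7), n1)
  expect_lte(rm_power_sample_size(0.40, m = 7, corr = 0.8), n1)
  expect_gte(rm_power_sample_size(0.40, m = 7, target_power = 0.99), n1)
  expect_gt(rm_anova_power(12, 0.4, 7), rm_anova_power(11, 0.4, 7))
  expect_error(rm_power_sample_size(1e-4, m = 2, n_max = 50),
               "non-convergence")
})

test_that("analytic power matches a simulated repeated-measures experiment", {
  # compound symmetry with total variance 1 and correlation 0.5; time
  # effects scaled to Cohen f = 0.40; 10,000 simulated cohorts of n = 11
  n <- rm_power_sample_size(0.40, m = 7)
  f <- 0.40; m <- 7; rho <- 0.5
  e <- c(-3, -2, -1, 0, 1, 2, 3)
  mu <- f * e / sqrt(mean(e^2))          # sum(mu^2)/m = f^2, total var 1
  set.seed(97)
  reps <- 10000
  rej <- logical(reps)
  crit <- stats::qf(0.95, m - 1, (n - 1) * (m - 1))
  for (r in seq_len(reps)) {
    y <- rep(stats::rnorm(n, 0, sqrt(rho)), m) +
      stats::rnorm(n * m, 0, sqrt(1 - rho)) +
      rep(mu, each = n)
    mm <- matrix(y, n, m)
    rej[r] <- rm_anova_oneway(mm)$F > crit
  }
  expect_lt(abs(mean(rej) - rm_anova_power(n, f, m, rho)), 0.01)
})
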