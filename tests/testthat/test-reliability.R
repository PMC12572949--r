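# ICC(3,1), SEM% and CV%: hand decompositions, independent model-fit
# oracles, and sampling properties.

test_that("two-way decomposition matches the hand-worked 2 x 2 case", {
  an <- two_way_anova(rbind(c(1, 1), c(3, 3)))
  expect_equal(an$bms, 4)
  expect_equal(an$rms, 0)
  expect_equal(an$ems, 0)
  expect_equal(an$sse, an$ems * an$df_error)
  icc <- icc_3_1(an)
  expect_identical(icc$icc, 1)
  expect_true(icc$degenerate)
})

test_that("decomposition agrees with an independent two-way linear model fit", {
  set.seed(31)
  for (rep in 1:3) {
    x <- matrix(rnorm(60, 3, 0.4), 20, 3)
    an <- two_way_anova(x)
    d <- data.frame(y = as.vector(x),
                    subj = factor(rep(1:20, 3)),
                    read = factor(rep(1:3, each = 20)))
    a <- anova(lm(y ~ subj + read, data = d))
    expect_equal(an$ssb, a["subj", "Sum Sq"], tolerance = 1e-10)
    expect_equal(an$ssr, a["read", "Sum Sq"], tolerance = 1e-10)
    expect_equal(an$sse, a["Residuals", "Sum Sq"], tolerance = 1e-10)
    expect_equal(an$df_error, a["Residuals", "Df"])
  }
})

test_that("ICC(3,1) formula arithmetic and threshold flag", {
  an <- list(n = 100, k = 3, bms = 0.2725, ems = 0.0025,
             df_error = 198, sse = 0.0025 * 198, degenerate = FALSE)
  icc <- icc_3_1(an)
  expect_equal(icc$icc, 0.27 / 0.2775, tolerance = 1e-12)
  expect_true(icc$ci_low <= icc$icc && icc$icc <= icc$ci_high)
  expect_true(icc$lower_one_sided > icc$ci_low)
  expect_true(icc$acceptable)
})

test_that("SEM% arithmetic and chi-square interval", {
  an <- list(n = 100, k = 3, ems = 0.0025, sse = 0.0025 * 198,
             df_error = 198, grand_mean = 3.19)
  s <- sem_pct(an)
  expect_equal(s$sem_mm, 0.05)
  expect_equal(s$sem_pct, 100 * 0.05 / 3.19, tolerance = 1e-12)
  expect_true(s$ci_low < s$sem_pct && s$sem_pct < s$ci_high)
  expect_true(s$acceptable)
  an0 <- list(n = 10, k = 3, ems = 0, sse = 0, df_error = 18,
              grand_mean = 3)
  expect_equal(sem_pct(an0)$sem_pct, 0)
})

test_that("CV% reduces to 100 s in the small-s limit and flags bad cells", {
  set.seed(17)
  n <- 4000
  mu <- rnorm(n, log(3.2), 0.1)
  x <- exp(mu + matrix(rnorm(3 * n, 0, 0.02), n, 3))
  cv <- cv_pct_log(x)
  expect_equal(cv$cv_pct, 100 * sqrt(expm1(0.02^2)), tolerance = 0.05)
  expect_equal(100 * sqrt(expm1(0.0004)), 2.0004, tolerance = 1e-4)
  # identical readings per subject -> zero within-subject variability
  y <- matrix(rep(exp(mu[1:10]), 3), 10, 3)
  expect_equal(cv_pct_log(y)$cv_pct, 0)
  bad <- x[1:5, ]; bad[3, 2] <- -1
  expect_error(cv_pct_log(bad), "row 3, reading 2")
})

test_that("CV% and SEM% agree for small log-normal variability", {
  set.seed(19)
  n <- 2000
  mu <- exp(rnorm(n, log(3.19), 0.09))
  x <- mu * exp(matrix(rnorm(3 * n, 0, 0.03), n, 3))
  fit <- icc_reliability(x)
  expect_lt(abs(fit$cv$cv_pct - fit$sem$sem_pct) / fit$cv$cv_pct, 0.10)
})

test_that("ICC is affine-invariant; SEM scales with the data", {
  set.seed(23)
  x <- matrix(rnorm(90, 3.2, 0.3), 30, 3) + rnorm(30, 0, 0.4)
  f1 <- icc_reliability(x)
  f2 <- icc_reliability(2.5 * x + 7)
  expect_equal(f2$icc$icc, f1$icc$icc, tolerance = 1e-12)
  expect_equal(f2$icc$ci_low, f1$icc$ci_low, tolerance = 1e-12)
  f3 <- icc_reliability(2.5 * x)
  expect_equal(f3$sem$sem_mm, 2.5 * f1$sem$sem_mm, tolerance = 1e-12)
  expect_equal(f3$sem$sem_pct, f1$sem$sem_pct, tolerance = 1e-12)
})

test_that("ICC estimator is unbiased and its CI calibrated at planned 0.95", {
  set.seed(29)
  n <- 100; k <- 3
  b_sd <- 0.30; w_sd <- b_sd * sqrt(0.05 / 0.95)  # planned ICC 0.95
  runs <- 500
  est <- numeric(runs); cover <- logical(runs)
  for (i in seq_len(runs)) {
    x <- 3.19 + rnorm(n, 0, b_sd) + matrix(rnorm(n * k, 0, w_sd), n, k)
    icc <- icc_3_1(two_way_anova(x))
    est[i] <- icc$icc
    cover[i] <- icc$ci_low <= 0.95 && 0.95 <= icc$ci_high
  }
  expect_lt(abs(mean(est) - 0.95), 0.01)
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})
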