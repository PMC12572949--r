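# Synthetic cohort generator: determinism, moment recovery, variance
# components.

test_that("generation is bit-reproducible under a fixed seed", {
  sp <- cohort_spec(data.frame(site = "lateral", mean_mm = 3.38),
                    n_per_group = 20, seed = 99)
  expect_identical(make_cohort(sp), make_cohort(sp))
  sp2 <- cohort_spec(data.frame(site = "lateral", mean_mm = 3.38),
                     n_per_group = 20, seed = 100)
  expect_false(identical(make_cohort(sp)$thickness_mm,
                         make_cohort(sp2)$thickness_mm))
})

test_that("zero within-subject SD gives identical readings and ICC 1", {
  sp <- cohort_spec(data.frame(site = "s", mean_mm = 3.2),
                    between_sd = 0.3, within_sd = 0, n_per_group = 30,
                    seed = 3)
  co <- make_cohort(sp)
  m <- readings_matrix(co, site = "s")
  expect_true(all(m[, 1] == m[, 2] & m[, 2] == m[, 3]))
  fit <- icc_reliability(m)
  expect_identical(fit$icc$icc, 1)
  expect_true(fit$icc$degenerate)
})

test_that("sample moments converge to the specified ones at large n", {
  # sample SDs of 10,000 subjects fluctuate by ~0.7% (1 sigma), so the 1%
  # convergence check is made on the average over five generator seeds
  moments <- vapply(1:5, function(s) {
    sp <- cohort_spec(data.frame(site = "s", mean_mm = 3.19),
                      between_sd = 0.30, within_sd = 0.05,
                      n_per_group = 10000, seed = s)
    sm <- subject_means(make_cohort(sp))
    c(mean(sm$thickness_mm), sd(sm$thickness_mm))
  }, numeric(2))
  expect_equal(mean(moments[1, ]), 3.19, tolerance = 0.01)
  # subject means carry between variance + within variance / k
  expect_equal(mean(moments[2, ]), sqrt(0.09 + 0.0025 / 3), tolerance = 0.01)
})

test_that("estimated ICC recovers the planned variance ratio", {
  sp <- cohort_spec(data.frame(site = "s", mean_mm = 3.19),
                    between_sd = 0.30, within_sd = 0.05,
                    n_per_group = 200, seed = 11)
  expect_equal(planned_icc(sp), 0.09 / 0.0925, tolerance = 1e-12)
  fit <- icc_reliability(make_cohort(sp), site = "s")
  expect_equal(fit$icc$icc, 0.973, tolerance = 0.02)
})

test_that("exact-moments mode hits requested group moments exactly", {
  g <- male_right_medial_groups()
  sp <- cohort_spec(g, seed = 21, exact_moments = TRUE)
  sm <- subject_means(make_cohort(sp))
  for (i in seq_len(nrow(g))) {
    v <- sm$thickness_mm[sm$age_group == g$age_group[i]]
    expect_length(v, g$n[i])
    expect_equal(mean(v), g$mean_mm[i], tolerance = 1e-12)
    expect_equal(sd(v), g$sd_mm[i], tolerance = 1e-12)
  }
})

test_that("a table-calibrated cohort yields an F near the recomputed value", {
  g <- data.frame(age_group = c("young", "middle_aged", "older", "retirement"),
                  site = "lateral", side = "right",
                  mean_mm = c(3.468, 3.271, 3.312, 3.481),
                  sd_mm = c(0.420, 0.338, 0.374, 0.376),
                  n = c(56L, 70L, 47L, 59L))
  # exact-moments: F equals the summary recomputation to floating precision
  sm <- subject_means(make_cohort(cohort_spec(g, seed = 8,
                                              exact_moments = TRUE)))
  a_raw <- anova_raw(sm$thickness_mm, sm$age_group)
  a_sum <- anova_from_summary(data.frame(group = g$age_group, n = g$n,
                                         mean = g$mean_mm, sd = g$sd_mm))
  expect_equal(a_raw$F, a_sum$F, tolerance = 1e-9)
  # random mode: F scatters around that value across seeds
  fs <- vapply(1:20, function(s) {
    smr <- subject_means(make_cohort(cohort_spec(g, seed = s,
                                                 within_sd = 0.05)))
    anova_raw(smr$thickness_mm, smr$age_group)$F
  }, numeric(1))
  expect_gt(mean(fs), 1)          # clearly non-null on average
  expect_lt(abs(median(fs) - a_sum$F) / a_sum$F, 1)
})

test_that("subjects share their random effect across sites", {
  g <- data.frame(site = c("lateral", "medial"), mean_mm = c(3.4, 3.3))
  co <- make_cohort(cohort_spec(g, between_sd = 0.3, within_sd = 0,
                                n_per_group = 50, seed = 13))
  sm <- subject_means(co)
  lat <- sm[sm$site == "lateral", ]
  med <- sm[sm$site == "medial", ]
  med <- med[match(lat$subject_id, med$subject_id), ]
  expect_equal(lat$thickness_mm - 3.4, med$thickness_mm - 3.3,
               tolerance = 1e-12)
})

test_that("spec validation rejects inconsistent cohorts", {
  g <- data.frame(site = "s", mean_mm = 3)
  expect_error(cohort_spec(g, between_sd = -1), "SDs")
  expect_error(cohort_spec(g, n_readings = 1), "n_readings")
  expect_error(cohort_spec(g, exact_moments = TRUE), "sd_mm")
  expect_error(cohort_spec(data.frame(x = 1)), "mean_mm")
})
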