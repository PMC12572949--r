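# Group-comparison engines: summary vs raw pairing and independent base-R
# oracles.

test_that("summary-statistics ANOVA equals the raw engine on its own moments", {
  set.seed(51)
  g <- factor(rep(1:4, times = c(14, 19, 11, 16)))
  y <- rnorm(length(g), 3.2 + 0.1 * as.integer(g), 0.35)
  a_raw <- anova_raw(y, g)
  a_sum <- anova_from_summary(a_raw$groups)
  for (f in c("ssb", "ssw", "msb", "msw", "F", "p"))
    expect_equal(a_sum[[f]], a_raw[[f]], tolerance = 1e-12)
  # and against base aov as an independent oracle
  a_aov <- summary(aov(y ~ g))[[1]]
  expect_equal(a_raw$F, a_aov["g", "F value"], tolerance = 1e-10)
  expect_equal(a_raw$p, a_aov["g", "Pr(>F)"], tolerance = 1e-10)
})

test_that("identical groups give F = 0, p = 1; zero variance flags", {
  s <- data.frame(group = c("a", "b"), n = c(10, 10),
                  mean = c(3, 3), sd = c(0.2, 0.2))
  a <- anova_from_summary(s)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  s0 <- data.frame(group = c("a", "b"), n = c(5, 5),
                   mean = c(1, 2), sd = c(0, 0))
  expect_warning(a0 <- anova_from_summary(s0), "infinite")
  expect_identical(a0$F, Inf)
})

test_that("Tukey-Kramer p values match base TukeyHSD on raw data", {
  set.seed(53)
  g <- factor(rep(letters[1:4], times = c(23, 27, 22, 28)))
  y <- rnorm(length(g), c(a = 3.3, b = 3.4, c = 3.3, d = 3.7)[g], 0.4)
  tk <- tukey_hsd(anova_raw(y, g))
  base <- TukeyHSD(aov(y ~ g))$g
  key <- paste(tk$pairs$group_2, tk$pairs$group_1, sep = "-")
  expect_equal(tk$pairs$p, unname(base[key, "p adj"]), tolerance = 1e-8)
  # identical groups: q = 0, p = 1
  s <- data.frame(group = 1:2, n = c(8, 8), mean = c(3, 3), sd = c(0.2, 0.2))
  expect_equal(tukey_hsd(s)$pairs$p, 1)
})

test_that("reported pair directions always match the sign of the mean difference", {
  set.seed(59)
  for (rep in 1:10) {
    g <- factor(rep(1:4, each = 15))
    y <- rnorm(60, sample(c(3, 3.2, 3.4, 3.6)), 0.3)
    tk <- tukey_hsd(anova_raw(y, g))
    m <- tapply(y, g, mean)
    for (i in seq_len(nrow(tk$pairs))) {
      hi <- sub(" >.*", "", tk$pairs$pair[i])
      lo <- sub(".*> ", "", tk$pairs$pair[i])
      expect_gte(m[hi], m[lo])
    }
  }
})

test_that("pooled and Welch t tests reproduce base t.test from raw data", {
  set.seed(61)
  x <- rnorm(40, 3.2, 0.3); y <- rnorm(55, 3.35, 0.42)
  tp <- t_between(x, y, variant = "pooled")
  tw <- t_between(x, y, variant = "welch")
  bp <- t.test(x, y, var.equal = TRUE)
  bw <- t.test(x, y)
  expect_equal(unname(tp$statistic), unname(bp$statistic), tolerance = 1e-12)
  expect_equal(tp$p, bp$p.value, tolerance = 1e-12)
  expect_equal(unname(tw$statistic), unname(bw$statistic), tolerance = 1e-12)
  expect_equal(tw$df, unname(bw$parameter), tolerance = 1e-9)
  # summary engine from the same moments is identical
  s <- data.frame(group = c("x", "y"), n = c(40, 55),
                  mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))
  expect_equal(t_between(s)$p, tp$p, tolerance = 1e-12)
  # equal groups
  expect_equal(t_between(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Mann-Whitney: exact enumeration and tie-corrected approximation", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p, 0.1)   # 2 * 1/20 over all C(6,3) orderings
  expect_true(mw$exact)
  # one adjacent transposition raises U to 1
  expect_equal(unname(mann_whitney(c(1, 2, 4), c(3, 5, 6))$statistic), 1)
  # ties route to the corrected normal approximation, matching wilcox.test
  set.seed(67)
  x <- round(rnorm(30, 3, 0.3), 1); y <- round(rnorm(25, 3.2, 0.3), 1)
  mw2 <- mann_whitney(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_false(mw2$exact)
  expect_equal(mw2$p, ref$p.value, tolerance = 1e-12)
  # degenerate: everything tied
  expect_equal(mann_whitney(rep(1, 5), rep(1, 7))$p, 1)
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula with ties", {
  y <- c(2.1, 2.3, 2.3, 2.8, 2.9, 2.6, 3.1, 3.0, 2.3)
  g <- rep(1:3, each = 3)
  kw <- kruskal_wallis_posthoc(y, g)
  r <- rank(y); N <- length(y)
  h_raw <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  ties <- table(y)
  h_oracle <- h_raw / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(unname(kw$statistic), h_oracle, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(h_oracle, 2, lower.tail = FALSE), tolerance = 1e-12)
  # Bonferroni adjustment over all pairs
  expect_equal(kw$pairs$p, pmin(1, kw$pairs$p_unadjusted * 3), tolerance = 1e-12)
  # degenerate
  expect_equal(kruskal_wallis_posthoc(rep(2, 9), g)$p, 1)
})

test_that("rank-based power grows with the shift alternative", {
  set.seed(71)
  power_at <- function(shift) {
    mean(vapply(1:60, function(i) {
      y <- c(rnorm(20), rnorm(20, shift), rnorm(20, 2 * shift))
      kruskal_wallis_posthoc(y, rep(1:3, each = 20))$p < 0.05
    }, logical(1)))
  }
  p0 <- power_at(0.1); p1 <- power_at(0.5); p2 <- power_at(1.0)
  expect_lt(p0, p1)
  expect_lte(p1, p2)
})

test_that("Brown-Forsythe gate matches car::leveneTest and detects 10x SD", {
  skip_if_not_installed("car")
  set.seed(73)
  g <- factor(rep(1:4, each = 50))
  y <- rnorm(200, 3, c(0.3, 0.3, 0.3, 3)[g])
  vh <- variance_homogeneity(y, g)
  lv <- car::leveneTest(y ~ g, center = median)
  expect_equal(unname(vh$statistic), lv[1, "F value"], tolerance = 1e-10)
  expect_equal(vh$p, lv[1, "Pr(>F)"], tolerance = 1e-10)
  expect_false(vh$homogeneous)
  expect_lt(vh$p, 1e-6)
  # mean-centred variant reduces to Levene's original test
  vm <- variance_homogeneity(y, g, center = "mean")
  lm_ <- car::leveneTest(y ~ g, center = mean)
  expect_equal(vm$p, lm_[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("homogeneity gate passes about 95% of equal-variance simulations", {
  set.seed(79)
  pass <- vapply(1:300, function(i) {
    g <- factor(rep(1:4, each = 40))
    variance_homogeneity(rnorm(160, 3, 0.3), g)$homogeneous
  }, logical(1))
  expect_gte(mean(pass), 0.90)
  expect_lte(mean(pass), 0.99)
  # constant groups: statistic 0, gate passes
  vh0 <- variance_homogeneity(rep(c(1, 2), each = 5), rep(1:2, each = 5))
  expect_true(vh0$homogeneous)
  expect_equal(unname(vh0$statistic), 0)
})

test_that("Shapiro-Wilk gate routes by distribution shape", {
  z <- qnorm(ppoints(100))
  expect_gt(unname(normality_gate(z)$statistic), 0.99)
  expect_true(normality_gate(z)$normal)
  set.seed(83)
  expect_false(normality_gate(runif(500))$normal)
  heavy_rej <- mean(vapply(1:60, function(i)
    !normality_gate(rt(100, df = 2))$normal, logical(1)))
  expect_gt(heavy_rej, 0.5)
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("Fisher exact matches a direct hypergeometric enumeration on 2x2", {
  tab <- matrix(c(1, 11, 9, 3), 2)
  fe <- fisher_exact_rxc(tab)
  # enumeration oracle: all tables with the same margins
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(max(0, k - n_):min(k, m), m, n_, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n_, k) * (1 + 1e-7)])
  expect_equal(fe$p, p_oracle, tolerance = 1e-9)
  expect_equal(fe$p, 0.00276, tolerance = 1e-3)
  # proportional rows: independence, p = 1
  expect_equal(fisher_exact_rxc(matrix(c(10, 20, 5, 10), 2))$p, 1)
  # empty margins dropped with warning
  expect_warning(fisher_exact_rxc(matrix(c(3, 0, 5, 2, 0, 7), 3)), "empty")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Monte-Carlo Fisher path is seeded and close to the exact value", {
  tab <- matrix(c(120, 80, 90, 110), 2)  # total 400 forces the MC path
  f1 <- fisher_exact_rxc(tab, exact_total = 300, B = 2e4, seed = 5)
  f2 <- fisher_exact_rxc(tab, exact_total = 300, B = 2e4, seed = 5)
  expect_identical(f1$p, f2$p)
  exact <- fisher.test(tab)$p.value
  expect_equal(f1$p, exact, tolerance = 0.05)
})

test_that("parametric statistics are affine-invariant, rank tests monotone-invariant", {
  set.seed(89)
  y <- rnorm(60, 3.2, 0.3); g <- factor(rep(1:3, each = 20))
  a <- 2.7; b <- -1.3
  expect_equal(anova_raw(a * y + b, g)$F, anova_raw(y, g)$F, tolerance = 1e-9)
  x1 <- y[g == 1]; x2 <- y[g == 2]
  expect_equal(t_between(a * x1 + b, a * x2 + b)$p, t_between(x1, x2)$p,
               tolerance = 1e-9)
  expect_equal(mann_whitney(exp(x1), exp(x2))$p, mann_whitney(x1, x2)$p,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis_posthoc(exp(y), g)$p,
               kruskal_wallis_posthoc(y, g)$p, tolerance = 1e-12)
})

test_that("significant-pair strings compress winners and mark tiers", {
  pairs <- data.frame(pair = c("4 > 1", "4 > 2", "3 > 1"),
                      p = c(0.01, 0.0005, 0.2))
  expect_identical(cartizone:::sig_pair_string(pairs), "4 > (1,2)")
  expect_identical(cartizone:::sig_pair_string(pairs[3, , drop = FALSE]), "NS")
  expect_identical(cartizone:::sig_marker(c(0.04, 0.0005, 0.5)),
                   c("*", "**", ""))
  expect_identical(format_p(c(0.0004, 0.096)), c("<0.001", "0.096"))
})
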