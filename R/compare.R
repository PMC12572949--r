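# Between-group inference with matched summary-statistics and raw-data
# engines, so analyses can be reproduced either from subject-level data or
# from published per-group (n, mean, SD) tables.

new_comparison <- function(method, statistic, df, p, ..., tiers = c(0.05, 0.001)) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   tiers = tiers), list(...)),
            class = "comparison_result")
}

#' Format a p value in table style
#' @param p numeric p value(s).
#' @param digits decimals shown.
#' @param floor values below `10^-digits` print as `"<0.001"` style.
#' @return character vector.
#' @export
format_p <- function(p, digits = 3, floor = 10^(-digits)) {
  ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
         formatC(p, digits = digits, format = "f"))
}

sig_marker <- function(p, tiers = c(0.05, 0.001)) {
  tiers <- sort(tiers, decreasing = TRUE)
  out <- rep("", length(p))
  for (i in seq_along(tiers)) out[p < tiers[i]] <- strrep("*", i)
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$method, "\n")
  stat <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
                collapse = ", ")
  dfs <- if (length(x$df)) paste0(", df = ", paste(signif(x$df, 6), collapse = ", ")) else ""
  cat("  ", stat, dfs, ", p = ", format_p(x$p), sig_marker(x$p, x$tiers),
      "\n", sep = "")
  if (!is.null(x$pairs) && nrow(x$pairs)) {
    cat("  post hoc pairs:\n")
    df <- x$pairs
    df$p_fmt <- paste0(format_p(df$p), sig_marker(df$p, x$tiers))
    print(df[, c("pair", "diff", "p_fmt")], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

check_summary_df <- function(s) {
  s <- as.data.frame(s)
  need <- c("group", "n", "mean", "sd")
  if (!all(need %in% names(s)))
    stop("summary needs columns group, n, mean, sd", call. = FALSE)
  if (nrow(s) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(s$n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (any(s$sd < 0)) stop("group SDs must be non-negative", call. = FALSE)
  s$group <- as.character(s$group)
  s
}

#' One-way ANOVA from per-group summary statistics
#'
#' Recomputes the classical one-way ANOVA table from per-group
#' `(n, mean, sd)` alone: `SSB = sum n_i (m_i - m)^2` about the weighted
#' grand mean and `SSW = sum (n_i - 1) s_i^2`. This makes the F statistics
#' of published group tables reproducible without subject-level data.
#'
#' @param s data frame with columns `group`, `n`, `mean`, `sd`.
#' @return Object of class `anova_table`: list with `ssb`, `ssw`,
#'   `df_between`, `df_within`, `msb`, `msw`, `F`, `p`, `grand_mean` and the
#'   group table.
#' @examples
#' s <- data.frame(group = c("a", "b"), n = c(10, 10),
#'                 mean = c(3, 3.2), sd = c(0.3, 0.3))
#' anova_from_summary(s)
#' @export
anova_from_summary <- function(s) {
  s <- check_summary_df(s)
  k <- nrow(s); N <- sum(s$n)
  gm <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - gm)^2)
  ssw <- sum((s$n - 1) * s$sd^2)
  df_b <- k - 1L; df_w <- N - k
  msb <- ssb / df_b; msw <- ssw / df_w
  if (msw == 0) {
    warning("zero within-group variance: F is infinite", call. = FALSE)
    Fv <- if (ssb > 0) Inf else NaN
    p <- if (ssb > 0) 0 else NA_real_
  } else {
    Fv <- msb / msw
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(ssb = ssb, ssw = ssw, df_between = df_b, df_within = df_w,
                 msb = msb, msw = msw, F = Fv, p = p, grand_mean = gm,
                 groups = s, engine = "summary"),
            class = "anova_table")
}

#' One-way ANOVA on raw group data
#'
#' Classical decomposition computed from subject-level values via a linear
#' model fit; agrees with [anova_from_summary()] applied to the sample
#' moments of the same data.
#'
#' @param values numeric vector of observations.
#' @param group grouping vector of the same length.
#' @return An `anova_table`, as for [anova_from_summary()].
#' @export
anova_raw <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  fit <- stats::lm(values ~ group)
  a <- stats::anova(fit)
  s <- data.frame(group = levels(group),
                  n = as.integer(table(group)),
                  mean = tapply(values, group, mean),
                  sd = tapply(values, group, stats::sd))
  rownames(s) <- NULL
  msw <- a$`Mean Sq`[2L]
  structure(list(ssb = a$`Sum Sq`[1L], ssw = a$`Sum Sq`[2L],
                 df_between = a$Df[1L], df_within = a$Df[2L],
                 msb = a$`Mean Sq`[1L], msw = msw,
                 F = if (msw == 0) Inf else a$`F value`[1L],
                 p = if (msw == 0) 0 else a$`Pr(>F)`[1L],
                 grand_mean = mean(values), groups = s, engine = "raw"),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s engine), %d groups, N = %d\n",
              x$engine, nrow(x$groups), sum(x$groups$n)))
  cat(sprintf("  F(%d, %d) = %.3f, p = %s\n", x$df_between, x$df_within,
              x$F, format_p(x$p)))
  invisible(x)
}

#' Tukey HSD (Tukey--Kramer) pairwise comparisons
#'
#' Studentized-range pairwise tests after a one-way ANOVA, from summary
#' moments alone: for groups i, j the statistic is
#' `q = |m_i - m_j| / sqrt(MSW / 2 (1/n_i + 1/n_j))` referred to the
#' studentized range with `(k, N - k)` parameters (the Kramer form for
#' unequal group sizes).
#'
#' @param x an `anova_table`, or a summary data frame as for
#'   [anova_from_summary()].
#' @param tiers significance tiers marked `*`, `**`, ... in reports.
#' @return A `comparison_result` whose `pairs` element has one row per
#'   unordered pair: `pair` (direction label such as `"4 > 2"` written
#'   larger-mean group first), `diff`, `q`, `p`, `significant`.
#' @examples
#' s <- data.frame(group = 1:3, n = c(20, 20, 20),
#'                 mean = c(3.0, 3.0, 3.4), sd = c(0.3, 0.3, 0.3))
#' tukey_hsd(s)$pairs
#' @export
tukey_hsd <- function(x, tiers = c(0.05, 0.001)) {
  if (!inherits(x, "anova_table")) x <- anova_from_summary(x)
  g <- x$groups
  k <- nrow(g)
  idx <- utils::combn(k, 2L)
  pairs <- apply(idx, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    d <- g$mean[i] - g$mean[j]
    se <- sqrt(x$msw / 2 * (1 / g$n[i] + 1 / g$n[j]))
    q <- abs(d) / se
    p <- stats::ptukey(q, k, x$df_within, lower.tail = FALSE)
    hi <- if (d >= 0) i else j; lo <- if (d >= 0) j else i
    data.frame(pair = paste(g$group[hi], ">", g$group[lo]),
               group_1 = g$group[i], group_2 = g$group[j],
               diff = d, q = q, p = p)
  })
  pairs <- do.call(rbind, pairs)
  pairs$significant <- pairs$p < max(tiers)
  new_comparison("Tukey HSD (Tukey-Kramer) post hoc",
                 statistic = c(q_max = max(pairs$q)),
                 df = c(k, x$df_within), p = min(pairs$p),
                 pairs = pairs, omnibus = x, tiers = tiers)
}

#' Independent two-sample t test from summary or raw data
#'
#' @param x,y either two numeric vectors of raw values, or `x` a two-row
#'   summary data frame (`group`, `n`, `mean`, `sd`) with `y` missing.
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return A `comparison_result` with the t statistic, df, two-sided p and
#'   the mean difference (first group minus second).
#' @examples
#' s <- data.frame(group = c("female", "male"), n = c(132, 100),
#'                 mean = c(2.856, 2.911), sd = c(0.243, 0.262))
#' t_between(s)  # p close to 0.10
#' @export
t_between <- function(x, y = NULL, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (is.null(y)) {
    s <- check_summary_df(x)
    if (nrow(s) != 2L) stop("t test needs exactly 2 groups", call. = FALSE)
  } else {
    s <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                    mean = c(mean(x), mean(y)),
                    sd = c(stats::sd(x), stats::sd(y)))
  }
  n1 <- s$n[1L]; n2 <- s$n[2L]
  d <- s$mean[1L] - s$mean[2L]
  if (s$sd[1L] == 0 && s$sd[2L] == 0) {
    if (d == 0)
      return(new_comparison("Independent t test (degenerate: zero variance)",
                            c(t = 0), df = n1 + n2 - 2, p = 1,
                            diff = 0, degenerate = TRUE))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s$sd[1L]^2 + (n2 - 1) * s$sd[2L]^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s$sd[1L]^2 / n1; v2 <- s$sd[2L]^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  new_comparison(sprintf("Independent t test (%s variant)", variant),
                 c(t = t), df = df, p = p, diff = d,
                 direction = paste(s$group[if (d >= 0) 1L else 2L], ">",
                                   s$group[if (d >= 0) 2L else 1L]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact enumeration when both samples
#' have at most `exact_max` values and no ties, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric vectors.
#' @param exact_max sample-size limit for the exact null distribution.
#' @return A `comparison_result` with the U statistic (count of (x, y)
#'   pairs with x ahead of y) and two-sided p.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 10L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L)
    return(new_comparison("Mann-Whitney U test (degenerate: all values tied)",
                          c(U = length(x) * length(y) / 2), df = numeric(0),
                          p = 1, degenerate = TRUE))
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  new_comparison(
    if (exact) "Mann-Whitney U test (exact)"
    else "Mann-Whitney U test (tie-corrected normal approximation)",
    c(U = unname(wt$statistic)), df = numeric(0), p = wt$p.value,
    exact = exact)
}

#' Kruskal-Wallis test with Dunn-Bonferroni post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p on k - 1 degrees of
#' freedom, followed by Dunn's pairwise rank-mean z tests with Bonferroni
#' adjustment over all unordered pairs.
#'
#' @param values numeric observations.
#' @param group grouping vector.
#' @param tiers significance tiers for report markers.
#' @return A `comparison_result`; `pairs` holds Dunn z, unadjusted and
#'   Bonferroni-adjusted p, and direction labels based on mean ranks.
#' @export
kruskal_wallis_posthoc <- function(values, group, tiers = c(0.05, 0.001)) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(new_comparison("Kruskal-Wallis (degenerate: all values tied)",
                          c(H = 0), df = k - 1L, p = 1, degenerate = TRUE))
  }
  kw <- stats::kruskal.test(values, group)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, group, mean)
  n <- as.integer(table(group))
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr  # Dunn's tie-corrected rank variance
  idx <- utils::combn(k, 2L)
  m <- ncol(idx)
  pairs <- apply(idx, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    d <- rbar[i] - rbar[j]
    z <- d / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    p <- 2 * stats::pnorm(-abs(z))
    hi <- if (d >= 0) i else j; lo <- if (d >= 0) j else i
    data.frame(pair = paste(levels(group)[hi], ">", levels(group)[lo]),
               group_1 = levels(group)[i], group_2 = levels(group)[j],
               diff_mean_rank = d, z = z, p_unadjusted = p,
               p = min(1, p * m))
  })
  pairs <- do.call(rbind, pairs)
  pairs$significant <- pairs$p < max(tiers)
  new_comparison("Kruskal-Wallis with Dunn-Bonferroni post hoc",
                 c(H = unname(kw$statistic)), df = k - 1L, p = kw$p.value,
                 pairs = pairs, tiers = tiers)
}

#' Variance-homogeneity gate (Brown-Forsythe)
#'
#' Levene-type test on absolute deviations from the group centres
#' (medians by default, the Brown-Forsythe variant; means by flag). The
#' boolean gate routes age-group comparisons to ANOVA + Tukey when variances
#' are homogeneous and to Kruskal-Wallis + Dunn-Bonferroni otherwise.
#'
#' @param values numeric observations.
#' @param group grouping vector.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @param alpha gate level.
#' @return A `comparison_result` with `homogeneous` (the gate) and the
#'   underlying F test.
#' @export
variance_homogeneity <- function(values, group, center = c("median", "mean"),
                                 alpha = 0.05) {
  center <- match.arg(center)
  group <- factor(group)
  cfun <- if (center == "median") stats::median else mean
  centers <- tapply(values, group, cfun)
  dev <- abs(values - centers[as.integer(group)])
  if (all(dev == 0)) {
    return(new_comparison("Brown-Forsythe variance homogeneity (constant groups)",
                          c(F = 0), df = c(nlevels(group) - 1L,
                                           length(values) - nlevels(group)),
                          p = 1, homogeneous = TRUE, center = center))
  }
  a <- anova_raw(dev, group)
  new_comparison(sprintf("Levene variance homogeneity (%s-centred)", center),
                 c(F = a$F), df = c(a$df_between, a$df_within), p = a$p,
                 homogeneous = a$p >= alpha, center = center)
}

#' Shapiro-Wilk normality gate
#'
#' Routes sex comparisons to the t test (and mean ± SD reporting) when the
#' sample is compatible with normality, and to Mann-Whitney (median, IQR)
#' otherwise.
#'
#' @param values numeric sample, 3 to 5000 observations.
#' @param alpha gate level.
#' @return A `comparison_result` with `normal` (the gate decision) and the
#'   W statistic.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  sw <- stats::shapiro.test(values)
  new_comparison("Shapiro-Wilk normality test",
                 c(W = unname(sw$statistic)), df = numeric(0),
                 p = sw$p.value, normal = sw$p.value >= alpha)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Exact (Freeman-Halton) p by the network algorithm when the table total
#' is small enough, Monte-Carlo otherwise with a stated replicate count and
#' seed.
#'
#' @param tab matrix of non-negative integer counts. Empty rows/columns are
#'   dropped with a warning.
#' @param exact_total largest table total for which the exact enumeration is
#'   attempted.
#' @param B Monte-Carlo replicates when enumeration is infeasible.
#' @param seed seed used for the Monte-Carlo path.
#' @return A `comparison_result` with the two-sided p and `method_detail`.
#' @examples
#' fisher_exact_rxc(matrix(c(1, 11, 9, 3), 2))  # p ~ 0.00276
#' @export
fisher_exact_rxc <- function(tab, exact_total = 300L, B = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping empty rows/columns from the contingency table",
            call. = FALSE)
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (any(dim(tab) < 2L))
    stop("need at least a 2 x 2 table after dropping empty margins",
         call. = FALSE)
  exact <- sum(tab) <= exact_total
  ft <- if (exact) stats::fisher.test(tab) else
    with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
  new_comparison(
    if (exact) "Fisher's exact test (Freeman-Halton enumeration)"
    else sprintf("Fisher's exact test (Monte-Carlo, B = %d, seed = %d)",
                 as.integer(B), as.integer(seed)),
    statistic = c(p = ft$p.value), df = numeric(0), p = ft$p.value,
    exact = exact)
}
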