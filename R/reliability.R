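#' Two-way repeated-measures ANOVA decomposition
#'
#' Decomposes an n subjects x k readings matrix into between-subjects,
#' between-readings and residual components, the table underlying the
#' consistency ICC(3,1), SEM% and log-method CV%.
#'
#' @param x numeric matrix, subjects in rows, readings in columns; complete
#'   (rows with missing cells are dropped beforehand, see
#'   [readings_matrix()]).
#' @return List with `n`, `k`, sums of squares `ssb` (subjects), `ssr`
#'   (readings), `sse` (residual), `sst`, mean squares `bms`, `rms`, `ems`,
#'   the degrees of freedom, `grand_mean`, and a `degenerate` flag set when
#'   the total variance is zero.
#' @examples
#' two_way_anova(rbind(c(1, 1), c(3, 3)))  # bms 4, rms 0, ems 0
#' @export
two_way_anova <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("readings matrix must be complete", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 readings", call. = FALSE)
  gm <- mean(x)
  subj <- rowMeans(x)
  read <- colMeans(x)
  ssb <- k * sum((subj - gm)^2)
  ssr <- n * sum((read - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssb - ssr
  sse <- max(sse, 0)  # guard tiny negative round-off
  df_b <- n - 1L; df_r <- k - 1L; df_e <- (n - 1L) * (k - 1L)
  list(n = n, k = k,
       ssb = ssb, ssr = ssr, sse = sse, sst = sst,
       bms = ssb / df_b, rms = ssr / df_r, ems = sse / df_e,
       df_subjects = df_b, df_readings = df_r, df_error = df_e,
       grand_mean = gm, degenerate = sst == 0)
}

#' ICC(3,1) from a two-way decomposition
#'
#' Single-measurement consistency intraclass correlation from the two-way
#' mixed-effects model: `(BMS - EMS) / (BMS + (k - 1) EMS)`. The reader
#' (trial) mean square is excluded from the denominator, as consistency of
#' agreement requires. Confidence bounds use the standard F pivot
#' `F = BMS / EMS` with `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param an decomposition from [two_way_anova()].
#' @param conf two-sided confidence level (default 0.95; the one-sided lower
#'   bound always uses the same level one-sided).
#' @param threshold acceptability threshold compared against the one-sided
#'   lower bound.
#' @return List with `icc`, `ci_low`, `ci_high` (two-sided),
#'   `lower_one_sided`, `acceptable` (lower one-sided bound > threshold) and
#'   `degenerate`.
#' @export
icc_3_1 <- function(an, conf = 0.95, threshold = 0.70) {
  n <- an$n; k <- an$k
  if (an$ems == 0) {
    icc <- if (an$bms > 0) 1 else NA_real_
    return(list(icc = icc, ci_low = icc, ci_high = icc,
                lower_one_sided = icc,
                acceptable = isTRUE(icc > threshold), degenerate = TRUE))
  }
  icc <- (an$bms - an$ems) / (an$bms + (k - 1) * an$ems)
  Fobs <- an$bms / an$ems
  a2 <- (1 - conf) / 2
  fl <- Fobs / stats::qf(1 - a2, n - 1, (n - 1) * (k - 1))
  fu <- Fobs * stats::qf(1 - a2, (n - 1) * (k - 1), n - 1)
  fl1 <- Fobs / stats::qf(conf, n - 1, (n - 1) * (k - 1))
  from_f <- function(f) (f - 1) / (f + k - 1)
  list(icc = icc, ci_low = from_f(fl), ci_high = from_f(fu),
       lower_one_sided = from_f(fl1),
       acceptable = from_f(fl1) > threshold,
       degenerate = isTRUE(an$degenerate))
}

#' SEM% from a two-way decomposition
#'
#' The standard error of measurement is the square root of the residual
#' mean square; SEM% expresses it as a percentage of the grand mean. Its
#' confidence interval follows from the chi-square distribution of
#' `SSE / sigma^2` on `(n - 1)(k - 1)` degrees of freedom.
#'
#' @param an decomposition from [two_way_anova()].
#' @param grand_mean mm; defaults to the decomposition's grand mean.
#' @param conf confidence level.
#' @param acceptable_below SEM% threshold regarded as minimal random error.
#' @return List with `sem_mm`, `sem_pct`, `ci_low`, `ci_high` (percent) and
#'   `acceptable`.
#' @export
sem_pct <- function(an, grand_mean = an$grand_mean, conf = 0.95,
                    acceptable_below = 10) {
  if (grand_mean <= 0) stop("grand mean must be positive", call. = FALSE)
  sem <- sqrt(an$ems)
  pct <- 100 * sem / grand_mean
  df <- an$df_error
  a2 <- (1 - conf) / 2
  lo <- 100 / grand_mean * sqrt(an$sse / stats::qchisq(1 - a2, df))
  hi <- 100 / grand_mean * sqrt(an$sse / stats::qchisq(a2, df))
  list(sem_mm = sem, sem_pct = pct, ci_low = lo, ci_high = hi,
       acceptable = pct < acceptable_below)
}

#' Within-subject CV% by the logarithmic method
#'
#' Natural-log transforms the readings, takes the residual variance
#' \eqn{s^2} of the same two-way decomposition on the log scale, and maps it
#' to the coefficient of variation of a log-normal error:
#' `CV% = 100 sqrt(exp(s^2) - 1)` (default), or the first-order variant
#' `100 (exp(s) - 1)`. Both reduce to `100 s` for small `s`. The interval
#' maps the chi-square interval of `s^2` through the same transform.
#'
#' @param x readings matrix (subjects x readings), strictly positive.
#' @param conf confidence level.
#' @param variant `"lognormal"` (default) or `"expm1"`.
#' @param acceptable_below CV% threshold regarded as small variability.
#' @return List with `cv_pct`, `ci_low`, `ci_high`, `s2_log` and
#'   `acceptable`.
#' @export
cv_pct_log <- function(x, conf = 0.95, variant = c("lognormal", "expm1"),
                       acceptable_below = 10) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive reading at subject row %d, reading %d; log method needs positive values",
      bad[1L], bad[2L]), call. = FALSE)
  }
  an <- two_way_anova(log(x))
  s2 <- an$ems
  df <- an$df_error
  a2 <- (1 - conf) / 2
  s2_lo <- an$sse / stats::qchisq(1 - a2, df)
  s2_hi <- an$sse / stats::qchisq(a2, df)
  to_cv <- switch(variant,
                  lognormal = function(v) 100 * sqrt(expm1(v)),
                  expm1 = function(v) 100 * expm1(sqrt(v)))
  list(cv_pct = to_cv(s2), ci_low = to_cv(s2_lo), ci_high = to_cv(s2_hi),
       s2_log = s2, acceptable = to_cv(s2) < acceptable_below)
}

#' Intra-rater reliability of triplicate readings
#'
#' One-stop reliability analysis of an n x k readings matrix: two-way
#' decomposition, consistency ICC(3,1) with two-sided interval and
#' one-sided lower bound, SEM% with chi-square interval, and log-method
#' CV%.
#'
#' @param x readings matrix (subjects in rows), or a `cartilage_cohort`
#'   together with filter arguments passed to [readings_matrix()].
#' @param site,side optional cohort filters when `x` is a cohort.
#' @param conf confidence level.
#' @param icc_threshold one-sided lower-bound acceptability threshold.
#' @param cv_variant passed to [cv_pct_log()].
#' @return Object of class `icc_reliability`: list with `anova`, `icc`,
#'   `sem`, `cv`, `n`, `k`, `grand_mean`, `site`.
#' @examples
#' sp <- cohort_spec(data.frame(site = "lateral", mean_mm = 3.19),
#'                   between_sd = 0.3, within_sd = 0.05,
#'                   n_per_group = 40, seed = 7)
#' fit <- icc_reliability(make_cohort(sp), site = "lateral")
#' fit
#' @export
icc_reliability <- function(x, site = NULL, side = NULL, conf = 0.95,
                            icc_threshold = 0.70,
                            cv_variant = "lognormal") {
  label <- paste(c(side, site), collapse = " ")
  if (inherits(x, "cartilage_cohort") ||
      (is.data.frame(x) && "thickness_mm" %in% names(x))) {
    x <- readings_matrix(x, site = site, side = side)
  }
  x <- as.matrix(x)
  an <- two_way_anova(x)
  res <- list(anova = an,
              icc = icc_3_1(an, conf = conf, threshold = icc_threshold),
              sem = sem_pct(an, conf = conf),
              cv = if (all(x > 0)) cv_pct_log(x, conf = conf,
                                              variant = cv_variant) else NULL,
              n = an$n, k = an$k, grand_mean = an$grand_mean,
              site = if (nzchar(label)) label else "all")
  class(res) <- "icc_reliability"
  res
}

#' @export
print.icc_reliability <- function(x, ...) {
  cat(sprintf("Intra-rater reliability [%s]: n = %d subjects, k = %d readings\n",
              x$site, x$n, x$k))
  cat(sprintf("  grand mean %.3f mm\n", x$grand_mean))
  cat(sprintf("  ICC(3,1) %.3f  (95%% CI %.3f-%.3f; one-sided lower %.3f%s)\n",
              x$icc$icc, x$icc$ci_low, x$icc$ci_high, x$icc$lower_one_sided,
              if (isTRUE(x$icc$acceptable)) ", acceptable" else ""))
  cat(sprintf("  SEM %.4f mm, SEM%% %.2f (95%% CI %.2f-%.2f)\n",
              x$sem$sem_mm, x$sem$sem_pct, x$sem$ci_low, x$sem$ci_high))
  if (!is.null(x$cv))
    cat(sprintf("  CV%% %.2f (95%% CI %.2f-%.2f)\n",
                x$cv$cv_pct, x$cv$ci_low, x$cv$ci_high))
  invisible(x)
}

#' @export
summary.icc_reliability <- function(object, ...) {
  an <- object$anova
  cat("Two-way decomposition:\n")
  tab <- data.frame(
    source = c("subjects", "readings", "error", "total"),
    df = c(an$df_subjects, an$df_readings, an$df_error,
           an$n * an$k - 1L),
    ss = c(an$ssb, an$ssr, an$sse, an$sst),
    ms = c(an$bms, an$rms, an$ems, NA))
  print(tab, row.names = FALSE, digits = 6)
  print(object)
  invisible(object)
}
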