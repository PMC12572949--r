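# Report assembly: normative summary tables, site-mean rollups and the
# formatted comparison tables.

#' Bundled normative summary tables
#'
#' Per-group summary statistics (n, mean, SD in mm) of distal femoral
#' cartilage thickness in healthy adults, measured by suprapatellar
#' ultrasound at six sites (right/left x lateral/middle/medial), as
#' published: by sex, and by age group (young 18-24, middle 25-44, older
#' 45-59, retirement >= 60) for all participants and within each sex, plus
#' the baseline age-group x sex counts. These tables are the inputs to the
#' summary-statistics engines; no subject-level data are distributed.
#'
#' @return List of data frames: `sex` (columns `side`, `site`, `sex`, `n`,
#'   `mean_mm`, `sd_mm`), `age_all`, `age_female`, `age_male` (columns
#'   `side`, `site`, `age_group`, `n`, `mean_mm`, `sd_mm`), and
#'   `baseline_counts` (columns `age_group`, `female`, `male`).
#' @export
normative_tables <- function() {
  dir <- system.file("extdata", package = "cartizone", mustWork = TRUE)
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(sex = rd("sex_summary.csv"),
       age_all = rd("age_groups_all.csv"),
       age_female = rd("age_groups_female.csv"),
       age_male = rd("age_groups_male.csv"),
       baseline_counts = rd("baseline_age_by_sex.csv"))
}

#' Roll site means up into knee, region and overall averages
#'
#' Site-level mean thicknesses are averaged with equal weight per site (the
#' mean of site means, not a subject-weighted mean): per knee within a
#' group, per region (site) across knees, and across all sites.
#'
#' @param s data frame with columns `side`, `site`, `mean_mm` (one row per
#'   site for one group, e.g. the "all" rows of the sex table).
#' @return List with `overall` (mm), `by_side` (named vector over sides)
#'   and `by_site` (named vector over sites).
#' @examples
#' tabs <- normative_tables()
#' rollup_site_means(tabs$sex[tabs$sex$sex == "female", ])$by_side
#' @export
rollup_site_means <- function(s) {
  s <- as.data.frame(s)
  stopifnot(all(c("side", "site", "mean_mm") %in% names(s)))
  if (anyDuplicated(s[, c("side", "site")]))
    stop("one row per side x site expected", call. = FALSE)
  list(overall = mean(s$mean_mm),
       by_side = tapply(s$mean_mm, s$side, mean),
       by_site = tapply(s$mean_mm, s$site, mean))
}

# Compact "4 > (1,2)" style description of significant post hoc pairs.
sig_pair_string <- function(pairs, alpha = 0.05) {
  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return("NS")
  win <- sub(" >.*$", "", sig$pair)
  los <- sub("^.*> ", "", sig$pair)
  parts <- vapply(unique(win), function(w) {
    l <- los[win == w]
    if (length(l) == 1L) paste(w, ">", l)
    else paste0(w, " > (", paste(sort(l), collapse = ","), ")")
  }, character(1))
  paste(parts, collapse = "; ")
}

#' Sex-comparison table from summary statistics
#'
#' One row per side x site with the pooled-t (or Welch) comparison of the
#' female and male groups, formatted as in normative reports: mean ± SD per
#' group, p to 3 decimals with `<0.001` flooring and significance markers.
#'
#' @param sex_tab data frame in the layout of `normative_tables()$sex`.
#' @param variant t-test variant, see [t_between()].
#' @param tiers significance tiers.
#' @return Data frame with formatted columns plus numeric `t` and `p`.
#' @export
compare_sex_summary <- function(sex_tab, variant = "pooled",
                                tiers = c(0.05, 0.001)) {
  key <- unique(sex_tab[, c("side", "site")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- sex_tab$side == key$side[i] & sex_tab$site == key$site[i]
    d <- sex_tab[sel, ]
    pick <- function(sx) d[d$sex == sx, ]
    f <- pick("female"); m <- pick("male"); a <- pick("all")
    ct <- t_between(data.frame(group = c("female", "male"),
                               n = c(f$n, m$n), mean = c(f$mean_mm, m$mean_mm),
                               sd = c(f$sd_mm, m$sd_mm)), variant = variant)
    data.frame(side = key$side[i], site = key$site[i],
               all = msd(a$mean_mm, a$sd_mm),
               female = msd(f$mean_mm, f$sd_mm),
               male = msd(m$mean_mm, m$sd_mm),
               t = unname(ct$statistic), p = ct$p,
               p_label = paste0(format_p(ct$p), sig_marker(ct$p, tiers)))
  })
  do.call(rbind, rows)
}

msd <- function(m, s) sprintf("%.3f ± %.3f", m, s)

#' Age-group comparison table from summary statistics
#'
#' One row per side x site: per-group mean ± SD, the ANOVA F recomputed
#' from the moments, and the Tukey-Kramer significant-pair string.
#'
#' @param age_tab data frame in the layout of `normative_tables()$age_all`.
#' @param tiers significance tiers.
#' @return Data frame with formatted group columns plus numeric `F`, `p`
#'   and `sig_pairs`.
#' @export
compare_age_summary <- function(age_tab, tiers = c(0.05, 0.001)) {
  key <- unique(age_tab[, c("side", "site")])
  groups <- unique(age_tab$age_group)
  rows <- lapply(seq_len(nrow(key)), function(i) {
    d <- age_tab[age_tab$side == key$side[i] & age_tab$site == key$site[i], ]
    d <- d[match(groups, d$age_group), ]
    s <- data.frame(group = seq_along(groups), n = d$n,
                    mean = d$mean_mm, sd = d$sd_mm)
    a <- anova_from_summary(s)
    tk <- tukey_hsd(a, tiers = tiers)
    row <- data.frame(side = key$side[i], site = key$site[i])
    for (j in seq_along(groups))
      row[[paste0("gr", j)]] <- msd(d$mean_mm[j], d$sd_mm[j])
    row$F <- a$F
    row$p <- a$p
    row$p_label <- paste0(format_p(a$p), sig_marker(a$p, tiers))
    row$sig_pairs <- sig_pair_string(tk$pairs, alpha = max(tiers))
    row
  })
  do.call(rbind, rows)
}

#' Assemble the full summary-statistics report
#'
#' Runs the sex comparison, the three age-group comparisons and the
#' site-mean rollups on a set of normative summary tables (the bundled ones
#' by default) and returns them as one report object.
#'
#' @param tabs list of tables as returned by [normative_tables()].
#' @param variant t-test variant for the sex comparison.
#' @param tiers significance tiers.
#' @return Object of class `cartilage_report`: list with `sex_comparison`,
#'   `age_all`, `age_female`, `age_male`, `rollups` and `baseline`.
#' @examples
#' rep <- build_report()
#' rep$rollups$overall_mm
#' @export
build_report <- function(tabs = normative_tables(), variant = "pooled",
                         tiers = c(0.05, 0.001)) {
  all_rows <- tabs$sex[tabs$sex$sex == "all", ]
  per_sex <- lapply(c(female = "female", male = "male"), function(sx) {
    rollup_site_means(tabs$sex[tabs$sex$sex == sx, ])
  })
  rollups <- list(
    overall_mm = rollup_site_means(all_rows)$overall,
    by_site_mm = rollup_site_means(all_rows)$by_site,
    by_side_mm = rollup_site_means(all_rows)$by_side,
    female_by_side_mm = per_sex$female$by_side,
    male_by_side_mm = per_sex$male$by_side)
  baseline <- NULL
  if (!is.null(tabs$baseline_counts)) {
    cnt <- as.matrix(tabs$baseline_counts[, c("female", "male")])
    rownames(cnt) <- tabs$baseline_counts$age_group
    baseline <- fisher_exact_rxc(cnt)
  }
  structure(list(
    sex_comparison = compare_sex_summary(tabs$sex, variant = variant,
                                         tiers = tiers),
    age_all = compare_age_summary(tabs$age_all, tiers = tiers),
    age_female = compare_age_summary(tabs$age_female, tiers = tiers),
    age_male = compare_age_summary(tabs$age_male, tiers = tiers),
    rollups = rollups, baseline = baseline, tiers = tiers),
    class = "cartilage_report")
}

#' @export
print.cartilage_report <- function(x, ...) {
  cat("Cartilage thickness report\n")
  cat(sprintf("  overall mean of site means: %.3f mm\n", x$rollups$overall_mm))
  cat("  by region (mm):",
      paste(sprintf("%s %.3f", names(x$rollups$by_site_mm),
                    x$rollups$by_site_mm), collapse = ", "), "\n")
  if (!is.null(x$baseline))
    cat(sprintf("  baseline age x sex: Fisher exact p = %s\n",
                format_p(x$baseline$p)))
  cat("\nSex comparison (t test):\n")
  print(x$sex_comparison[, c("side", "site", "female", "male", "p_label")],
        row.names = FALSE)
  cat("\nAge groups, all participants (ANOVA + Tukey):\n")
  print(x$age_all[, c("side", "site", "p_label", "sig_pairs")],
        row.names = FALSE)
  invisible(x)
}

#' Write a report to CSV and Markdown files
#'
#' @param report a `cartilage_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cartilage_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("sex_comparison", "age_all", "age_female", "age_male")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  ro <- report$rollups
  roll_df <- data.frame(
    quantity = c("overall",
                 paste0("site_", names(ro$by_site_mm)),
                 paste0("side_", names(ro$by_side_mm)),
                 paste0("female_side_", names(ro$female_by_side_mm)),
                 paste0("male_side_", names(ro$male_by_side_mm))),
    mean_mm = c(ro$overall_mm, ro$by_site_mm, ro$by_side_mm,
                ro$female_by_side_mm, ro$male_by_side_mm))
  p <- file.path(dir, "rollups.csv")
  utils::write.csv(roll_df, p, row.names = FALSE)
  paths <- c(paths, p)
  md <- file.path(dir, "report.md")
  writeLines(report_markdown(report), md)
  invisible(c(paths, md))
}

report_markdown <- function(report) {
  fmt_table <- function(df) {
    df <- as.data.frame(lapply(df, function(v)
      if (is.numeric(v)) signif(v, 5) else v))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"),
        character(1)))
  }
  c("# Cartilage thickness report", "",
    sprintf("Overall mean of site means: %.3f mm", report$rollups$overall_mm), "",
    "## Sex comparison", "",
    fmt_table(report$sex_comparison[, c("side", "site", "all", "female",
                                        "male", "p_label")]), "",
    "## Age groups (all participants)", "",
    fmt_table(report$age_all[, c("side", "site", "p_label", "sig_pairs")]), "",
    "## Age groups (females)", "",
    fmt_table(report$age_female[, c("side", "site", "p_label", "sig_pairs")]), "",
    "## Age groups (males)", "",
    fmt_table(report$age_male[, c("side", "site", "p_label", "sig_pairs")]))
}
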