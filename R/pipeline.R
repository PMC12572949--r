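# Cohort CSV i/o, run configuration and the umbrella pipeline.

cohort_columns <- c("subject_id", "sex", "age_group", "side", "site",
                    "reading_index", "thickness_mm")

#' Write a cohort table to CSV
#'
#' UTF-8, comma-separated, '.' decimal, header row; full precision on
#' `thickness_mm` so that write-then-read is an identity.
#'
#' @param cohort a `cartilage_cohort` (or data frame with its schema).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  d <- as.data.frame(cohort)[, cohort_columns]
  d$thickness_mm <- formatC(d$thickness_mm, digits = 17, format = "g")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Checks the schema of a triplicate-readings cohort file: required
#' columns, numeric positive thicknesses, integer reading indices. Schema
#' violations are reported with the offending row numbers.
#'
#' @param path CSV file with columns `subject_id`, `sex`, `age_group`,
#'   `side`, `site`, `reading_index`, `thickness_mm`.
#' @param allowed_sites,allowed_sex optional vectors of allowed labels;
#'   unknown labels raise an error naming the rows.
#' @return A validated `cartilage_cohort` data frame.
#' @export
read_cohort <- function(path, allowed_sites = NULL, allowed_sex = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(d))
  if (length(missing_cols))
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L) stop("cohort file has no data rows", call. = FALSE)
  bad_row <- function(cond, what) {
    if (any(cond))
      stop(sprintf("%s at row(s) %s", what,
                   paste(utils::head(which(cond), 5L), collapse = ", ")),
           call. = FALSE)
  }
  thick <- suppressWarnings(as.numeric(d$thickness_mm))
  bad_row(is.na(thick), "non-numeric thickness_mm")
  d$thickness_mm <- thick
  bad_row(d$thickness_mm <= 0, "non-positive thickness_mm")
  ri <- suppressWarnings(as.integer(d$reading_index))
  bad_row(is.na(ri) | ri < 1L, "invalid reading_index")
  d$reading_index <- ri
  if (!is.null(allowed_sites))
    bad_row(!d$site %in% allowed_sites, "unknown site label")
  if (!is.null(allowed_sex))
    bad_row(!d$sex %in% allowed_sex, "unknown sex label")
  structure(d, class = c("cartilage_cohort", "data.frame"))
}

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed recorded in every output.
#' @param cohort either a path to a cohort CSV or a [cohort_spec] to
#'   generate one.
#' @param half_width,fraction,convention zone-partition parameters (kept in
#'   the provenance record; used when images are quantified).
#' @param alpha significance level; `tiers` the report marker tiers.
#' @param t_variant,cv_variant engine options, see [t_between()] and
#'   [cv_pct_log()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cohort = NULL,
                       half_width = 4.8, fraction = 0.25,
                       convention = "absolute_mm", alpha = 0.05,
                       tiers = c(0.05, 0.001), t_variant = "pooled",
                       cv_variant = "lognormal") {
  stopifnot(alpha > 0, alpha < 1, all(tiers > 0), all(tiers < 1))
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 half_width = half_width, fraction = fraction,
                 convention = convention, alpha = alpha, tiers = tiers,
                 t_variant = t_variant, cv_variant = cv_variant),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, runs per-site intra-rater reliability,
#' between-sex and between-age-group comparisons on subject-level means
#' (with the variance-homogeneity gate routing each site to ANOVA + Tukey
#' or Kruskal-Wallis + Dunn-Bonferroni), rolls site means up, and writes
#' all tables plus a provenance JSON to the output directory. Outputs are
#' deterministic given the configuration and seed.
#'
#' @param config a [run_config].
#' @return Invisibly, a list with `cohort`, `reliability` (per side x
#'   site), `sex_comparisons`, `age_comparisons`, `rollups` and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- stage("load-cohort", {
    if (inherits(config$cohort, "cohort_spec")) make_cohort(config$cohort)
    else if (is.character(config$cohort)) read_cohort(config$cohort)
    else if (inherits(config$cohort, "cartilage_cohort")) config$cohort
    else stop("config$cohort must be a cohort_spec, a path, or a cohort",
              call. = FALSE)
  })
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  keys <- unique(as.data.frame(cohort)[, c("side", "site")])
  keys <- keys[order(keys$side, keys$site), , drop = FALSE]
  rel <- stage("reliability", {
    out <- list()
    for (i in seq_len(nrow(keys))) {
      out[[paste(keys$side[i], keys$site[i], sep = "_")]] <-
        icc_reliability(cohort, site = keys$site[i], side = keys$side[i],
                        cv_variant = config$cv_variant)
    }
    out
  })
  rel_df <- do.call(rbind, lapply(names(rel), function(nm) {
    r <- rel[[nm]]
    data.frame(site = nm, n = r$n, k = r$k,
               grand_mean_mm = r$grand_mean, icc = r$icc$icc,
               icc_low = r$icc$ci_low, icc_high = r$icc$ci_high,
               icc_lower_one_sided = r$icc$lower_one_sided,
               sem_pct = r$sem$sem_pct,
               cv_pct = if (is.null(r$cv)) NA_real_ else r$cv$cv_pct)
  }))
  utils::write.csv(rel_df, file.path(config$out_dir, "reliability.csv"),
                   row.names = FALSE)

  sm <- subject_means(cohort)
  sexes <- setdiff(unique(sm$sex), "all")
  comparisons <- stage("compare", {
    sex_cmp <- NULL
    if (length(sexes) == 2L) {
      sex_cmp <- lapply(seq_len(nrow(keys)), function(i) {
        d <- sm[sm$side == keys$side[i] & sm$site == keys$site[i], ]
        a <- d$thickness_mm[d$sex == sexes[1L]]
        b <- d$thickness_mm[d$sex == sexes[2L]]
        gate_ok <- length(a) >= 3 && length(b) >= 3 &&
          normality_gate(a, config$alpha)$normal &&
          normality_gate(b, config$alpha)$normal
        cmp <- if (gate_ok) t_between(a, b, variant = config$t_variant)
               else mann_whitney(a, b)
        list(side = keys$side[i], site = keys$site[i], test = cmp,
             groups = sexes, parametric = gate_ok)
      })
    }
    age_cmp <- NULL
    if (length(unique(sm$age_group)) >= 2L) {
      age_cmp <- lapply(seq_len(nrow(keys)), function(i) {
        d <- sm[sm$side == keys$side[i] & sm$site == keys$site[i], ]
        gate <- variance_homogeneity(d$thickness_mm, d$age_group,
                                     alpha = config$alpha)
        if (gate$homogeneous) {
          a <- anova_raw(d$thickness_mm, d$age_group)
          list(side = keys$side[i], site = keys$site[i], omnibus = a,
               posthoc = tukey_hsd(a, tiers = config$tiers), gate = gate)
        } else {
          kw <- kruskal_wallis_posthoc(d$thickness_mm, d$age_group,
                                       tiers = config$tiers)
          list(side = keys$side[i], site = keys$site[i], omnibus = kw,
               posthoc = kw, gate = gate)
        }
      })
    }
    list(sex = sex_cmp, age = age_cmp)
  })

  site_means <- aggregate(thickness_mm ~ side + site, data = sm, FUN = mean)
  names(site_means)[3L] <- "mean_mm"
  rollups <- rollup_site_means(site_means)
  roll_df <- data.frame(
    quantity = c("overall", paste0("side_", names(rollups$by_side)),
                 paste0("site_", names(rollups$by_site))),
    mean_mm = c(rollups$overall, rollups$by_side, rollups$by_site))
  utils::write.csv(roll_df, file.path(config$out_dir, "rollups.csv"),
                   row.names = FALSE)

  prov <- list(
    package = "cartizone",
    version = as.character(utils::packageVersion("cartizone")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    # out_dir is a machine-local path; excluded so identical runs produce
    # byte-identical provenance
    config = unclass(config)[setdiff(names(config), c("cohort", "out_dir"))],
    cohort_spec = if (inherits(config$cohort, "cohort_spec")) {
      sp <- config$cohort
      list(groups = sp$groups, between_sd = sp$between_sd,
           within_sd = sp$within_sd, n_per_group = sp$n_per_group,
           n_readings = sp$n_readings, seed = sp$seed,
           exact_moments = sp$exact_moments)
    } else NULL,
    timestamp = NULL)  # deliberately omitted so outputs are byte-stable
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(cohort = cohort, reliability = rel,
                 reliability_table = rel_df,
                 sex_comparisons = comparisons$sex,
                 age_comparisons = comparisons$age,
                 rollups = rollups, out_dir = config$out_dir))
}

# Wrap a pipeline stage so failures name the stage.
stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}
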