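#' Specify a synthetic measurement cohort
#'
#' Describes a cohort of subjects with triplicate thickness readings per
#' measurement site, generated under the additive two-way model
#' \deqn{y_{irs} = \mu_s + b_i + e_{ir},}
#' with subject effects \eqn{b_i \sim N(0, \sigma_b^2)} shared across sites
#' and reading errors \eqn{e_{ir} \sim N(0, \sigma_w^2)}. The planned
#' single-reading reliability is \eqn{ICC = \sigma_b^2 / (\sigma_b^2 +
#' \sigma_w^2)}.
#'
#' @param groups data frame with one row per group x site combination:
#'   grouping columns among `sex`, `age_group`, `side`, `site` (missing ones
#'   are filled with `"all"`), a `mean_mm` column, and optionally per-row
#'   `n` (subjects) and `sd_mm` (target between-subject SD, used by the
#'   exact-moments mode and as a per-row override of `between_sd`).
#' @param between_sd between-subject SD in mm.
#' @param within_sd within-subject (reading-to-reading) SD in mm.
#' @param n_per_group subjects per (sex, age_group) group, unless `groups$n`
#'   is given.
#' @param n_readings readings per subject and site (>= 2; the study protocol
#'   uses 3).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param exact_moments if `TRUE`, each group x site sample of subject-level
#'   values is affinely rescaled so its sample mean and SD equal `mean_mm`
#'   and `sd_mm` exactly, and all readings of a subject are identical. This
#'   makes summary-statistics and raw-data engines comparable bit for bit.
#' @return An object of class `cohort_spec`.
#' @seealso [make_cohort()], [planned_icc()]
#' @export
cohort_spec <- function(groups, between_sd = 0.30, within_sd = 0.05,
                        n_per_group = 50L, n_readings = 3L, seed = 1L,
                        exact_moments = FALSE) {
  groups <- as.data.frame(groups)
  if (!"mean_mm" %in% names(groups))
    stop("groups must contain a mean_mm column", call. = FALSE)
  for (col in c("sex", "age_group", "side", "site"))
    if (!col %in% names(groups)) groups[[col]] <- "all"
  if (anyDuplicated(groups[, c("sex", "age_group", "side", "site")]))
    stop("duplicate (sex, age_group, side, site) rows in groups", call. = FALSE)
  if (between_sd < 0 || within_sd < 0)
    stop("SDs must be non-negative", call. = FALSE)
  if (n_readings < 2L)
    stop("n_readings must be at least 2", call. = FALSE)
  if (exact_moments && !"sd_mm" %in% names(groups))
    stop("exact_moments mode needs a target sd_mm column in groups",
         call. = FALSE)
  if ("sd_mm" %in% names(groups) && any(groups$sd_mm < 0))
    stop("sd_mm targets must be non-negative", call. = FALSE)
  structure(list(groups = groups, between_sd = between_sd,
                 within_sd = within_sd, n_per_group = as.integer(n_per_group),
                 n_readings = as.integer(n_readings), seed = as.integer(seed),
                 exact_moments = isTRUE(exact_moments)),
            class = "cohort_spec")
}

#' Planned single-reading ICC of a cohort specification
#' @param spec a [cohort_spec] (or the two SDs).
#' @param between_sd,within_sd used when `spec` is missing.
#' @return The variance-ratio reliability in `[0, 1]`.
#' @export
planned_icc <- function(spec, between_sd, within_sd) {
  if (!missing(spec) && inherits(spec, "cohort_spec")) {
    between_sd <- spec$between_sd
    within_sd <- spec$within_sd
  }
  if (between_sd == 0 && within_sd == 0) return(NA_real_)
  between_sd^2 / (between_sd^2 + within_sd^2)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic cohort of triplicate readings
#'
#' Draws one row per subject x side x site x reading under the model in
#' [cohort_spec()]. Subjects are nested in (sex, age_group) groups and share
#' their random effect across sides and sites; readings within a subject and
#' site differ only by the within-subject error.
#'
#' @param spec a [cohort_spec].
#' @return Data frame of class `cartilage_cohort` with columns
#'   `subject_id`, `sex`, `age_group`, `side`, `site`, `reading_index`,
#'   `thickness_mm`, carrying the spec as attribute `cohort_spec`.
#' @examples
#' sp <- cohort_spec(data.frame(site = "lateral", mean_mm = 3.38),
#'                   between_sd = 0.3, within_sd = 0.05,
#'                   n_per_group = 5, seed = 42)
#' make_cohort(sp)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  subj_groups <- unique(g[, c("sex", "age_group")])
  k <- spec$n_readings
  with_seed(spec$seed, {
    rows <- vector("list", 0L)
    next_id <- 0L
    for (sg in seq_len(nrow(subj_groups))) {
      sgx <- subj_groups$sex[sg]
      sga <- subj_groups$age_group[sg]
      sites <- g[g$sex == sgx & g$age_group == sga, , drop = FALSE]
      n <- if ("n" %in% names(sites)) sites$n[1L] else spec$n_per_group
      ids <- sprintf("S%04d", next_id + seq_len(n))
      next_id <- next_id + n
      b <- rnorm(n, 0, spec$between_sd)
      for (r in seq_len(nrow(sites))) {
        bsd <- if ("sd_mm" %in% names(sites) && !spec$exact_moments &&
                   !is.na(sites$sd_mm[r])) sites$sd_mm[r] else NA_real_
        subj_val <- if (is.na(bsd)) sites$mean_mm[r] + b else
          sites$mean_mm[r] + b * (bsd / max(spec$between_sd,
                                            .Machine$double.eps))
        if (spec$exact_moments) {
          subj_val <- affine_to_moments(b, sites$mean_mm[r], sites$sd_mm[r])
          e <- matrix(0, n, k)
        } else {
          e <- matrix(rnorm(n * k, 0, spec$within_sd), n, k)
        }
        for (j in seq_len(k)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = ids, sex = sgx, age_group = sga,
            side = sites$side[r], site = sites$site[r],
            reading_index = j, thickness_mm = subj_val + e[, j])
        }
      }
    }
    out <- do.call(rbind, rows)
  })
  ord <- order(out$subject_id, out$side, out$site, out$reading_index)
  out <- out[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("cartilage_cohort", "data.frame"),
            cohort_spec = spec)
}

# Rescale a sample affinely so that mean(x) == m and sd(x) == s exactly.
affine_to_moments <- function(x, m, s) {
  sx <- stats::sd(x)
  if (sx == 0) return(rep(m, length(x)))
  m + (x - mean(x)) * (s / sx)
}

#' Pivot a cohort to a subjects x readings matrix for one site
#'
#' @param cohort a `cartilage_cohort` (or any data frame with the cohort
#'   schema).
#' @param site,side,sex,age_group optional filters; `NULL` keeps all levels.
#' @return Numeric matrix, one row per subject, one column per reading
#'   index, suitable for [icc_reliability()]. Subjects with incomplete
#'   readings are dropped with a message (complete-case rule).
#' @export
readings_matrix <- function(cohort, site = NULL, side = NULL, sex = NULL,
                            age_group = NULL) {
  d <- as.data.frame(cohort)
  for (f in c("site", "side", "sex", "age_group")) {
    v <- get(f)
    if (!is.null(v)) d <- d[d[[f]] %in% v, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no readings left after filtering", call. = FALSE)
  k <- max(d$reading_index)
  m <- tapply(d$thickness_mm, list(d$subject_id, d$reading_index),
              function(v) v[1L])
  complete <- rowSums(!is.na(m)) == k
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped for incomplete readings")
  m <- m[complete, , drop = FALSE]
  storage.mode(m) <- "double"
  m
}

#' Subject-level mean thickness per group
#'
#' Averages a subject's readings at a site, the value entering all
#' between-group comparisons.
#'
#' @param cohort a `cartilage_cohort`.
#' @return Data frame with one row per subject x side x site and columns
#'   `subject_id`, `sex`, `age_group`, `side`, `site`, `thickness_mm`.
#' @export
subject_means <- function(cohort) {
  d <- as.data.frame(cohort)
  agg <- aggregate(
    thickness_mm ~ subject_id + sex + age_group + side + site,
    data = d, FUN = mean)
  agg[order(agg$subject_id, agg$side, agg$site), , drop = FALSE]
}
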