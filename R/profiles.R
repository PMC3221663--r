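## Selection-pressure profiles: per-site omega from a fit, the average over
## key positions, the random-cohort null distribution, ligand-category rank
## tests and trend regressions.

#' Per-column omega profile from a fitted site model
#'
#' The naive empirical Bayes posterior-mean omega per alignment column.
#'
#' @param fit A `site_model_fit`.
#' @return Numeric vector of length `column_count`.
#' @export
site_omega_profile <- function(fit) {
  stopifnot(inherits(fit, "site_model_fit"))
  fit$neb_omega
}

#' Compare the key-position mean omega with a random-cohort null
#'
#' Draws `n_cohorts` cohorts of `cohort_size` columns (uniformly without
#' replacement within a cohort, with replacement across cohorts; key columns
#' included unless `exclude_key`), averages the omega profile over each, and
#' contrasts the key-position average with the resulting distribution.
#'
#' @param profile Numeric per-column omega profile.
#' @param key_columns Integer vector of key column indices.
#' @param n_cohorts Number of random cohorts (default 200).
#' @param cohort_size Positions per cohort (default 10).
#' @param seed Random seed (required).
#' @param exclude_key Exclude the key columns from the sampling pool?
#' @param subgroup_id Optional identifier carried through to reports.
#' @return A `cohort_comparison`: `omega_key_mean`, `random_means`,
#'   `random_mean`, `random_sd`, `z_offset`, `outside_2sigma`, `ratio`
#'   (key mean over the grand mean of the cohort means), `threshold_flag`
#'   (key mean > 0.1, the strong-negative-selection cutoff), plus the
#'   sampling settings.
#' @export
cohort_null <- function(profile, key_columns, n_cohorts = 200, cohort_size = 10,
                        seed, exclude_key = FALSE, subgroup_id = NA) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is.numeric(profile), length(key_columns) >= 1)
  pool <- seq_along(profile)
  if (exclude_key) pool <- setdiff(pool, key_columns)
  if (cohort_size > length(pool))
    stop("cohort_size exceeds the number of available columns")
  set.seed(seed)
  random_means <- vapply(seq_len(n_cohorts), function(i)
    mean(profile[sample(pool, cohort_size)]), numeric(1))
  okm <- mean(profile[key_columns])
  rm_ <- mean(random_means)
  rsd <- stats::sd(random_means)
  z <- if (rsd > 0) (okm - rm_) / rsd else 0
  structure(list(subgroup_id = subgroup_id, omega_key_mean = okm,
                 random_means = random_means, random_mean = rm_,
                 random_sd = rsd, z_offset = z,
                 outside_2sigma = abs(z) > 2,
                 ratio = if (rm_ > 0) okm / rm_ else NA_real_,
                 threshold_flag = okm > 0.1,
                 n_cohorts = n_cohorts, cohort_size = cohort_size,
                 seed = seed, exclude_key = exclude_key),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf(
    "cohort_comparison%s: <omega_key> = %.4f, random %.4f +/- %.4f (%d cohorts of %d)\n",
    if (is.na(x$subgroup_id)) "" else paste0(" [subgroup ", x$subgroup_id, "]"),
    x$omega_key_mean, x$random_mean, x$random_sd, x$n_cohorts, x$cohort_size))
  cat(sprintf("  z = %.2f%s; ratio = %.3f; omega_key > 0.1: %s\n", x$z_offset,
              if (x$outside_2sigma) " (outside 2 sigma)" else "",
              x$ratio, x$threshold_flag))
  invisible(x)
}

#' Kruskal-Wallis comparison of key-position omega across ligand categories
#'
#' @param omega_key Numeric vector of per-subgroup key-position mean omegas.
#' @param category Factor/character of ligand categories, same length.
#' @return List with the `stats::kruskal.test` result (`H`, `p_value`) and a
#'   per-category summary (n, mean rank, median omega).
#' @export
category_comparison <- function(omega_key, category) {
  category <- as.factor(as.character(category))
  if (nlevels(category) < 2) stop("need >= 2 categories")
  if (any(table(category) < 2)) stop("each category needs >= 2 values")
  if (length(unique(omega_key)) == 1) {
    ## fully tied data: no rank variation, H = 0 by convention
    kt <- list(statistic = c(H = 0), p.value = 1,
               parameter = c(df = nlevels(category) - 1))
  } else {
    kt <- stats::kruskal.test(omega_key, category)
  }
  rk <- rank(omega_key)
  summ <- do.call(rbind, lapply(levels(category), function(g) {
    i <- category == g
    data.frame(category = g, n = sum(i), mean_rank = mean(rk[i]),
               median_omega_key = stats::median(omega_key[i]))
  }))
  list(H = unname(kt$statistic), p_value = kt$p.value, df = unname(kt$parameter),
       summary = summ[order(summ$mean_rank), ])
}

#' Trend regressions over subgroup cohort comparisons
#'
#' Ordinary least squares of the key-position mean omega on the random-cohort
#' grand mean, and of their ratio on each mean (log10 scale), after excluding
#' the listed subgroups (by default those flagged as positively selected).
#'
#' @param comparisons List of `cohort_comparison` objects.
#' @param exclude Subgroup ids to exclude from the regressions.
#' @return List with the assembled `data` (one row per retained subgroup) and
#'   per-regression summaries (`slope`, `intercept`, `r_squared`, `p_value`).
#' @export
trend_report <- function(comparisons, exclude = NULL) {
  df <- do.call(rbind, lapply(comparisons, function(x)
    data.frame(subgroup_id = x$subgroup_id, omega_key = x$omega_key_mean,
               omega_random = x$random_mean, ratio = x$ratio,
               z = x$z_offset, outside_2sigma = x$outside_2sigma,
               flag_gt_0.1 = x$threshold_flag)))
  keep <- !(df$subgroup_id %in% exclude)
  d <- df[keep & is.finite(df$ratio) & df$omega_key > 0 & df$omega_random > 0, ]
  if (nrow(d) < 3) stop("fewer than 3 points after exclusions")
  summarize_lm <- function(f, data) {
    m <- stats::lm(f, data = data)
    s <- summary(m)
    list(slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
         r_squared = s$r.squared,
         p_value = unname(s$coefficients[2, 4]))
  }
  list(data = df,
       key_vs_random = summarize_lm(omega_key ~ omega_random, d),
       ratio_vs_key = summarize_lm(ratio ~ log10(omega_key), d),
       ratio_vs_random = summarize_lm(ratio ~ log10(omega_random), d),
       excluded = exclude)
}
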