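#' Pooled two-sample t test from summary statistics
#'
#' Student's independent-samples t test with pooled variance, computed from
#' each group's mean, SEM and n alone -- the form needed to re-test
#' contrasts reported only as `mean +/- SEM` summaries. The SEM is
#' converted back to a sample variance (`s^2 = sem^2 * n`), variances are
#' pooled with `df = n1 + n2 - 2`, and the two-sided p-value is returned.
#' The result is identical to a pooled t test on any raw sample having
#' those moments.
#'
#' @param mean1,sem1,n1 First group's mean, standard error of the mean, and
#'   sample size (n >= 2).
#' @param mean2,sem2,n2 Second group.
#' @return An object of classes `seizr_htest` and `htest` (statistic `t`,
#'   `parameter` df, `p.value`, `estimate`).
#' @examples
#' # Day-1 focal seizure counts, stimulated (n = 7) vs sham (n = 8)
#' pooled_t_from_summary(8.9, 1.7, 7, 25.1, 5.1, 8)
#' @export
pooled_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  if (sem1 < 0 || sem2 < 0) abort("SEMs must be >= 0")
  s1sq <- sem1^2 * n1
  s2sq <- sem2^2 * n2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
  delta <- mean1 - mean2
  if (sp2 == 0) {
    if (delta != 0)
      abort("zero pooled variance with unequal means: t is infinite")
    tstat <- 0
  } else {
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * pt(-abs(tstat), df)
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df), p.value = p,
         estimate = c(`mean difference` = delta),
         method = "Pooled two-sample t test from summary statistics",
         data.name = sprintf("group 1 (%g +/- %g, n=%d) vs group 2 (%g +/- %g, n=%d)",
                             mean1, sem1, n1, mean2, sem2, n2)),
    class = c("seizr_htest", "htest"))
}

#' Paired (dependent-samples) t test
#'
#' Two-sided paired Student t: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1` on the within-pair differences. Identical pairs return
#' `t = 0, p = 1`; zero-variance differences with a nonzero mean are
#' rejected (the statistic would be infinite).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return An object of classes `seizr_htest` and `htest`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort("`x` and `y` must have equal length >= 2")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) != 0)
      abort("zero-variance differences with nonzero mean: t is infinite")
    res <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                p.value = 1, estimate = c(`mean difference` = 0),
                method = "Paired t-test", data.name = "x and y")
  } else {
    ht <- stats::t.test(x, y, paired = TRUE)
    res <- list(statistic = ht$statistic, parameter = ht$parameter,
                p.value = ht$p.value, estimate = ht$estimate,
                method = "Paired t-test", data.name = "x and y")
  }
  structure(res, class = c("seizr_htest", "htest"))
}

#' @export
tidy.seizr_htest <- function(x, ...) {
  tibble::tibble(
    estimate = unname(x$estimate),
    statistic = unname(x$statistic),
    df = unname(x$parameter),
    p.value = x$p.value,
    method = x$method)
}

#' @export
glance.seizr_htest <- function(x, ...) tidy(x)

#' Two-way mixed (split-plot) repeated-measures ANOVA
#'
#' Fits the split-plot decomposition used for group-by-day seizure
#' parameters: a between-subject factor (treatment group, tested against
#' subjects-within-group error) and a within-subject factor (injection
#' day) plus their interaction (tested against the day-by-subject error
#' stratum). No sphericity correction is applied, so the within-subject
#' degrees of freedom are the uncorrected `(days - 1, (days - 1) * (n - g))`
#' -- e.g. `(2, 26)` for 15 subjects in 2 groups over 3 days, with the
#' group test on `(1, 13)`. The fit is delegated to [stats::aov()] with an
#' `Error(subject/within)` stratum.
#'
#' @param data Tibble in long format: one row per subject x day.
#' @param value,subject,within,between Bare column names of the response,
#'   the subject id, the within-subject factor (day) and the
#'   between-subject factor (group).
#' @return Object of class `rm_anova`; `tidy()` gives one row per effect
#'   (`term`, `df`, `df_error`, `sumsq`, `meansq`, `statistic`, `p.value`),
#'   `glance()` the design dimensions.
#' @export
mixed_rm_anova <- function(data, value, subject, within, between) {
  d <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    subject = factor(dplyr::pull(data, {{ subject }})),
    within = factor(dplyr::pull(data, {{ within }})),
    between = factor(dplyr::pull(data, {{ between }})))
  if (any(is.na(d$value))) abort("response contains missing values")
  # completeness: every subject must contribute every within-level once
  cells <- table(d$subject, d$within)
  if (any(cells != 1)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    msg <- if (nrow(bad)) {
      paste0("missing cells: ",
             paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
                   sep = ":", collapse = ", "))
    } else "duplicated subject x day rows"
    abort(paste0("incomplete repeated-measures table; ", msg))
  }
  grp_of <- tapply(as.character(d$between), d$subject, unique)
  if (any(lengths(grp_of) != 1))
    abort("each subject must belong to exactly one group")
  if (any(table(unlist(grp_of)) < 2))
    abort("need at least 2 subjects per group")

  fit <- stats::aov(value ~ between * within + Error(subject / within), data = d)
  sm <- summary(fit)
  # between-subject stratum: group effect vs subjects-within-group
  s_between <- sm[["Error: subject"]][[1]]
  s_within <- sm[["Error: subject:within"]][[1]]
  row_of <- function(tab, term) tab[trimws(rownames(tab)) == term, , drop = FALSE]
  res_b <- row_of(s_between, "Residuals")
  res_w <- row_of(s_within, "Residuals")
  # degenerate (zero-variance) strata: both SS vanish up to rounding
  eps <- 1e-10 * (sum(d$value^2) + 1)
  mk <- function(tab, term, res, label) {
    r <- row_of(tab, term)
    ss <- r[1, "Sum Sq"]; df <- r[1, "Df"]
    ss_e <- res[1, "Sum Sq"]; df_e <- res[1, "Df"]
    ms <- ss / df; ms_e <- ss_e / df_e
    f <- if (ss < eps && ss_e < eps) 0
      else if (ms_e == 0) Inf
      else ms / ms_e
    tibble::tibble(term = label, df = df, df_error = df_e,
                   sumsq = ss, meansq = ms, statistic = f,
                   p.value = pf(f, df, df_e, lower.tail = FALSE))
  }
  table <- dplyr::bind_rows(
    mk(s_between, "between", res_b, "group"),
    mk(s_within, "within", res_w, "day"),
    mk(s_within, "between:within", res_w, "group:day"))
  structure(
    list(table = table, fit = fit,
         n_subjects = nlevels(d$subject),
         n_groups = nlevels(d$between),
         n_within = nlevels(d$within)),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> split-plot, %d subjects in %d groups x %d levels\n",
              x$n_subjects, x$n_groups, x$n_within))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_groups = x$n_groups,
                 n_within = x$n_within)
}

#' Monte-Carlo power of the Day-1 group contrast
#'
#' Repeatedly draws synthetic cohorts from [generate_cohort()] and applies
#' the pooled two-sample t test to the Day-1 focal seizure counts,
#' returning the fraction of cohorts rejecting at level `alpha`. With the
#' null effect this estimates the test's type-I error; with the default
#' effect it estimates power for the observed group difference at the
#' original sample sizes.
#'
#' @param n_cohorts Number of simulated cohorts (>= 50).
#' @param n_per_group As in [generate_cohort()].
#' @param group_effect A [cohort_effect()] or `"none"`.
#' @param alpha Significance level. Default 0.05.
#' @param day Day whose focal counts are tested. Default 1.
#' @param seed Integer seed.
#' @return One-row tibble: `power` (rejection fraction), `n_cohorts`,
#'   `alpha`, `mc_se` (binomial Monte-Carlo standard error).
#' @export
recover_group_effect <- function(n_cohorts = 200,
                                 n_per_group = c(hfs = 7, sham = 8),
                                 group_effect = cohort_effect(),
                                 alpha = 0.05, day = 1, seed = 1L) {
  if (n_cohorts < 50) abort("use at least 50 simulated cohorts")
  rejections <- vapply(seq_len(n_cohorts), function(i) {
    co <- generate_cohort(n_per_group, days = max(1, day),
                          group_effect = group_effect,
                          seed = (seed * 10000L + i) %% .Machine$integer.max,
                          build_configs = FALSE)
    d1 <- co[co$day == day, ]
    groups <- unique(d1$group)
    x <- d1$n_focal_true[d1$group == groups[1]]
    y <- d1$n_focal_true[d1$group == groups[2]]
    stats::t.test(x, y, var.equal = TRUE)$p.value < alpha
  }, logical(1))
  p <- mean(rejections)
  tibble::tibble(power = p, n_cohorts = n_cohorts, alpha = alpha,
                 mc_se = sqrt(p * (1 - p) / n_cohorts))
}
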