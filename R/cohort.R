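#' Group-by-day effect descriptor for synthetic cohorts
#'
#' Describes the per-group, per-day distributions of the session-level
#' quantities the cohort generator draws: focal and generalized seizure
#' counts (normal, truncated to at least one event on Day 1 -- the injection
#' protocol re-doses until convulsive seizures appear, so every Day-1
#' session seizes) and the interictal spike rate. Defaults reproduce the
#' group-by-day means and standard deviations of a repeated low-dose
#' intrahippocampal kainate experiment comparing a responsively stimulated
#' group (n = 7) with sham controls (n = 8): Day-1 focal counts 8.9 +/- 4.5
#' vs 25.1 +/- 14.4 (mean +/- SD).
#'
#' @param focal_mean,focal_sd 2 x days matrices (rows `hfs`, `sham`) of
#'   focal-seizure count means and SDs.
#' @param generalized_mean,generalized_sd Same layout for generalized counts.
#' @param is_rate_mean,is_rate_sd Same layout for the interictal spike rate
#'   (spikes/min).
#' @return A list of class `cohort_effect`.
#' @export
cohort_effect <- function(
    focal_mean = rbind(hfs = c(8.9, 7.8, 6.2), sham = c(25.1, 6.1, 5.2)),
    focal_sd = rbind(hfs = c(4.5, 7.4, 7.4), sham = c(14.4, 6.5, 4.8)),
    generalized_mean = rbind(hfs = c(2.4, 2.3, 2.5), sham = c(1.7, 1.6, 2.7)),
    generalized_sd = rbind(hfs = c(1.6, 1.6, 2.6), sham = c(0.8, 1.4, 2.3)),
    is_rate_mean = rbind(hfs = c(4, 2.5, 2), sham = c(8, 5, 4)),
    is_rate_sd = rbind(hfs = c(1.5, 1, 1), sham = c(3, 2, 1.5))) {
  out <- list(focal_mean = focal_mean, focal_sd = focal_sd,
              generalized_mean = generalized_mean,
              generalized_sd = generalized_sd,
              is_rate_mean = is_rate_mean, is_rate_sd = is_rate_sd)
  structure(out, class = "cohort_effect")
}

#' Null (no-group-difference) cohort effect
#'
#' Both groups share the sham distributions; used for type-I-error
#' calibration of the downstream tests.
#' @return A `cohort_effect` with identical rows for both groups.
#' @export
cohort_effect_null <- function() {
  eff <- cohort_effect()
  for (nm in names(eff)) eff[[nm]]["hfs", ] <- eff[[nm]]["sham", ]
  eff
}

# normal draw truncated below (rejection sampling), rounded to integer counts
rtrunc_round <- function(n, mean, sd, lower) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lower) break
    }
    out[i] <- x
  }
  round(out)
}

#' Generate a labeled synthetic cohort of sessions
#'
#' Produces one session specification per rat and injection day, with group
#' and day labels and ground-truth session-level quantities drawn from a
#' [cohort_effect()] descriptor. Each row carries a [generator_config()]
#' (list column `config`) with a concrete non-overlapping seizure schedule,
#' so any individual session can be rendered to full EEG with
#' [generate_session()]; Monte-Carlo studies over many cohorts use the
#' ground-truth columns directly.
#'
#' @param n_per_group Named integer vector `c(hfs = ..., sham = ...)` (a
#'   single integer is recycled to both groups); each must be >= 2.
#' @param days Number of injection days (labels `1..days`). Default 3.
#' @param base_config [generator_config()] supplying the session template
#'   (sampling rate, duration, background, spike properties).
#' @param group_effect A [cohort_effect()], or `"none"` for the null effect.
#' @param seed Integer seed.
#' @param build_configs If `FALSE`, skip building per-session seizure
#'   schedules (faster; ground-truth columns only).
#' @return A tibble with one row per rat x day: `rat_id`, `group`, `day`,
#'   `n_focal_true`, `n_generalized_true`, `is_rate_true`, and (if built)
#'   `config`.
#' @export
generate_cohort <- function(n_per_group = c(hfs = 7, sham = 8),
                            days = 3,
                            base_config = generator_config(),
                            group_effect = cohort_effect(),
                            seed = 1L,
                            build_configs = TRUE) {
  if (identical(group_effect, "none")) group_effect <- cohort_effect_null()
  if (!inherits(group_effect, "cohort_effect"))
    abort("`group_effect` must be a cohort_effect() or \"none\"")
  if (length(n_per_group) == 1) n_per_group <- c(hfs = n_per_group, sham = n_per_group)
  if (any(n_per_group < 2)) abort("need at least 2 subjects per group")
  set.seed(seed)

  grid <- tidyr::expand_grid(
    group = rep(names(n_per_group), n_per_group),
    day = seq_len(days))
  grid$rat_id <- paste0(grid$group, "_",
                        rep(unlist(lapply(n_per_group, seq_len)), each = days))
  grid <- grid[, c("rat_id", "group", "day")]

  day_col <- function(m, g, d) m[g, min(d, ncol(m))]
  draw_row <- function(group, day) {
    eff <- group_effect
    lower <- if (day == 1) 0.5 else -0.49 # Day 1: every session seizes
    tibble::tibble(
      n_focal_true = rtrunc_round(1, day_col(eff$focal_mean, group, day),
                                  day_col(eff$focal_sd, group, day), lower),
      n_generalized_true = rtrunc_round(1, day_col(eff$generalized_mean, group, day),
                                        day_col(eff$generalized_sd, group, day), -0.49),
      is_rate_true = max(0, rnorm(1, day_col(eff$is_rate_mean, group, day),
                                  day_col(eff$is_rate_sd, group, day))))
  }
  draws <- purrr::map2(grid$group, grid$day, draw_row)
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(draws))

  if (build_configs) {
    out$config <- purrr::pmap(
      list(out$n_focal_true, out$n_generalized_true, out$is_rate_true,
           seq_len(nrow(out))),
      function(nf, ng, isr, i) {
        cfg <- base_config
        cfg$spike_rate <- isr
        cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
        cfg$seizure_schedule <- schedule_seizures(
          nf, ng, cfg$session_duration, cfg$baseline_quiet_s,
          cfg$seizure_ramp_s, cfg$seizure_amplitude_factor)
        cfg
      })
  }
  out
}

# lay out nf focal + ng generalized seizures without overlap; events are
# shuffled in time, durations drawn then shrunk if the session is crowded
schedule_seizures <- function(nf, ng, session_duration, quiet_s, ramp_s, amp_factor) {
  m <- nf + ng
  if (m == 0)
    return(tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                          class = character(), stage = character(),
                          generalization_delay_s = numeric()))
  cls <- sample(c(rep("focal", nf), rep("generalized", ng)))
  dur <- ifelse(cls == "focal", runif(m, 15, 40), runif(m, 30, 60))
  pre <- ramp_s * min(1, 1 / (amp_factor - 1))
  avail <- session_duration - quiet_s - 2 * pre
  gap <- pre + 2
  if (sum(dur) + m * gap > 0.9 * avail)
    dur <- dur * (0.9 * avail - m * gap) / sum(dur)
  slack <- avail - sum(dur) - m * gap
  gaps <- {g <- runif(m + 1); g / sum(g) * slack}
  onset <- quiet_s + pre + cumsum(gaps[seq_len(m)] + gap) +
    cumsum(c(0, head(dur, -1)))
  stage <- ifelse(cls == "focal",
                  sample(c("I", "II"), m, replace = TRUE),
                  sample(c("III", "IV", "V"), m, replace = TRUE))
  tibble::tibble(onset_s = onset, duration_s = dur, class = cls,
                 stage = stage, generalization_delay_s = 2)
}
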