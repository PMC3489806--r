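#' Per-session seizure and spike metrics
#'
#' Computes the session-level measurements the group-by-day analysis runs
#' on: focal/generalized seizure counts, latency of the first focal seizure
#' relative to the most recent preceding injection, total ictal durations by
#' class, log10-transformed inter-focal-seizure intervals, the interictal
#' spike (IS) rate, and whether the session reached stage V or status
#' epilepticus. The IS rate is spikes per minute counted over the 90-minute
#' session in which the first seizure occurred (the whole recording when no
#' seizure occurred), excluding spikes inside seizure intervals or
#' stimulation epochs -- interictal by definition.
#'
#' @param events A `seizure_events` tibble ([classify_seizures()] +
#'   [detect_status_epilepticus()]).
#' @param spikes A `spike_events` tibble ([detect_spikes()]).
#' @param annotation Session annotation carrying at least the injection
#'   times (`event_type == "injection"`); stage and HFS rows are used when
#'   present.
#' @param rat_id,group,day Optional session labels copied into the output.
#' @param session_minutes Length of one post-injection monitoring session
#'   in minutes. Default 90.
#' @param session_duration Recording length in seconds; defaults to the
#'   annotation's recorded duration or, failing that, the last event offset.
#' @param log_base Base of the inter-seizure-interval log transform.
#'   Default 10 (intervals of 100-250 s map to log values of 2.0-2.4).
#' @param interval_convention `"onset"` (onset-to-onset, default) or
#'   `"offset"` (previous offset to next onset) for inter-focal intervals.
#' @return One-row tibble of class `session_metrics` with the fields above;
#'   `inter_focal_log` is a list column of the per-gap log-intervals.
#' @export
compute_session_metrics <- function(events, spikes, annotation,
                                    rat_id = NA_character_,
                                    group = NA_character_, day = NA_integer_,
                                    session_minutes = 90,
                                    session_duration = NULL,
                                    log_base = 10,
                                    interval_convention = c("onset", "offset")) {
  interval_convention <- match.arg(interval_convention)
  ev <- dplyr::arrange(tibble::as_tibble(events), .data$onset_s)
  spk <- tibble::as_tibble(spikes)
  ann <- tibble::as_tibble(annotation)
  inj <- annotation_events(ann, "injection")$onset_s
  if (length(inj) == 0)
    abort("annotation carries no injection time; metrics are referenced to injections")
  hfs <- annotation_events(ann, "hfs")
  session_duration <- session_duration %||%
    attr(annotation, "session_duration") %||%
    max(c(ev$offset_s, spk$offset_s, session_minutes * 60), na.rm = TRUE)

  n_focal <- sum(ev$class == "focal")
  n_gen <- sum(ev$class == "generalized")
  n_uncl <- sum(ev$class == "unclassified")

  latency <- NA_real_
  focal_on <- ev$onset_s[ev$class == "focal"]
  if (n_focal >= 1) {
    ref <- max(inj[inj <= focal_on[1]], -Inf)
    if (!is.finite(ref)) ref <- min(inj)
    latency <- focal_on[1] - ref
  }

  inter_log <- numeric(0)
  if (n_focal >= 2) {
    gaps <- if (interval_convention == "onset") {
      diff(focal_on)
    } else {
      focal_off <- ev$offset_s[ev$class == "focal"]
      focal_on[-1] - focal_off[-n_focal]
    }
    inter_log <- log(gaps, base = log_base)
  }

  # IS-rate window: the 90-min session containing the first seizure
  if (nrow(ev) > 0) {
    first_on <- ev$onset_s[1]
    w0 <- max(inj[inj <= first_on], -Inf)
    if (!is.finite(w0)) w0 <- 0
  } else {
    w0 <- 0
  }
  w1 <- min(w0 + session_minutes * 60, session_duration)
  in_window <- spk$onset_s >= w0 & spk$onset_s < w1
  ictal <- rep(FALSE, nrow(spk))
  for (i in seq_len(nrow(ev)))
    ictal <- ictal | (spk$onset_s < ev$offset_s[i] & spk$offset_s > ev$onset_s[i])
  for (i in seq_len(nrow(hfs)))
    ictal <- ictal | (spk$onset_s < hfs$offset_s[i] & spk$offset_s > hfs$onset_s[i])
  is_rate <- sum(in_window & !ictal) / ((w1 - w0) / 60)

  stages <- annotation_events(ann, "stage")
  reached_v <- any(stage_to_int(stages$label) == 5L)
  if ("stage" %in% names(ev) && nrow(ev) > 0)
    reached_v <- reached_v || any(stage_to_int(ev$stage) == 5L, na.rm = TRUE)
  reached_se <- any(ev$is_se %||% FALSE)

  out <- tibble::tibble(
    rat_id = rat_id, group = group, day = day,
    n_focal = n_focal, n_generalized = n_gen, n_unclassified = n_uncl,
    latency_focal = latency,
    dur_focal_total = sum(ev$duration_s[ev$class == "focal"]),
    dur_generalized_total = sum(ev$duration_s[ev$class == "generalized"]),
    isi_log_mean = if (length(inter_log)) mean(inter_log) else NA_real_,
    inter_focal_log = list(inter_log),
    is_rate = is_rate,
    reached_stage_v = reached_v, reached_se = reached_se)
  class(out) <- c("session_metrics", class(out))
  out
}

#' Aggregate session metrics into a group-by-day summary
#'
#' Produces the mean, SEM (`sd/sqrt(n)`) and n for every metric in each
#' group-by-day cell, in the layout of a seizure-parameter summary table.
#' Values that are missing by definition (e.g. the latency of a session
#' with no focal seizure) are excluded and counted in `n_missing`; cells
#' with a single contributing session report `NA` SEM.
#'
#' @param sessions Tibble of per-session metrics (rows from
#'   [compute_session_metrics()], or any tibble with `group`, `day` and
#'   numeric metric columns).
#' @param metrics Character vector of metric columns to summarize; defaults
#'   to the standard set present in `sessions`.
#' @return A tibble of class `group_summary`: `metric`, `group`, `day`,
#'   `n`, `mean`, `sem`, `n_missing`.
#' @export
aggregate_day_metrics <- function(sessions,
                                  metrics = c("n_focal", "n_generalized",
                                              "latency_focal",
                                              "dur_focal_total",
                                              "dur_generalized_total",
                                              "isi_log_mean", "is_rate")) {
  s <- tibble::as_tibble(sessions)
  if (nrow(s) == 0) abort("`sessions` is empty")
  metrics <- intersect(metrics, names(s))
  if (!length(metrics)) abort("no metric columns found in `sessions`")
  long <- tidyr::pivot_longer(s[, c("group", "day", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$metric, .data$group, .data$day) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (sum(!is.na(.data$value)) > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
      sem = if (sum(!is.na(.data$value)) > 1)
        sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
      else NA_real_,
      n_missing = sum(is.na(.data$value)),
      .groups = "drop")
  class(out) <- c("group_summary", class(out))
  out
}

#' Seizure-severity counts from a stage-per-injection table
#'
#' Summarizes a per-rat, per-day, per-injection table of behavioural
#' Racine stages (up to four injections per day; missing cells mean fewer
#' injections) into the per-day counts used to describe cohort severity:
#' rats whose maximum stage that day was V, rats flagged as having reached
#' status epilepticus, and rats whose maximum stage stayed below III (no
#' generalized, i.e. no convulsive, seizures).
#'
#' @param stage_table Tibble with columns `rat_id`, `day`, `injection`,
#'   `stage` (Racine `"I"`..`"V"`, or `NA` for injections not given), `se`
#'   (logical SE flag per injection), and optionally `group`.
#' @return Tibble with one row per (group x) day: `n_rats`, `reached_v`,
#'   `reached_se`, `no_generalized`.
#' @export
table1_counts <- function(stage_table) {
  st <- tibble::as_tibble(stage_table)
  needed <- c("rat_id", "day", "stage")
  if (!all(needed %in% names(st)))
    abort("stage_table needs columns rat_id, day, stage (and optionally se, group)")
  if (!"se" %in% names(st)) st$se <- FALSE
  st$se[is.na(st$se)] <- FALSE
  st$stage_int <- stage_to_int(st$stage)
  grp_vars <- intersect(c("group", "day"), names(st))
  per_rat <- st |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_vars, "rat_id")))) |>
    dplyr::summarise(max_stage = suppressWarnings(max(.data$stage_int, na.rm = TRUE)),
                     any_se = any(.data$se), .groups = "drop")
  per_rat$max_stage[!is.finite(per_rat$max_stage)] <- NA_integer_
  per_rat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::summarise(
      n_rats = dplyr::n(),
      reached_v = sum(.data$max_stage == 5L, na.rm = TRUE),
      reached_se = sum(.data$any_se),
      no_generalized = sum(.data$max_stage < 3L, na.rm = TRUE),
      .groups = "drop")
}

#' Bundled example severity table (sham arm)
#'
#' The per-injection Racine stages and status-epilepticus flags of the
#' eight sham-group rats of a published repeated low-dose intrahippocampal
#' kainate experiment (three injection days, up to four injections per
#' day), shipped as a plain-text fixture for [table1_counts()].
#'
#' @return Tibble with columns `rat_id`, `group`, `day`, `injection`,
#'   `stage`, `se`.
#' @export
example_racine_table <- function() {
  path <- system.file("extdata", "sham_racine_stages.csv", package = "seizr")
  readr::read_csv(path, col_types = readr::cols(
    rat_id = readr::col_character(), group = readr::col_character(),
    day = readr::col_integer(), injection = readr::col_integer(),
    stage = readr::col_character(), se = readr::col_logical()))
}
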