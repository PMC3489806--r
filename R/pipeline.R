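#' Run the full analysis pipeline on one session
#'
#' Executes the whole chain on a configuration: simulate (or read) a
#' two-channel session, estimate the baseline model, calibrate the
#' detection threshold against the truth annotation (when present), segment
#' seizures on both channels, classify them with the stage annotations and
#' flag status epilepticus, detect interictal spikes outside ictal and
#' stimulation intervals, compute session metrics, and write every stage's
#' output (CSV/JSON) plus a reproducibility log (config hash, seed,
#' package version) to `out_dir`. The run is deterministic under a fixed
#' seed.
#'
#' @param config A list, or path to a YAML file, with (all optional)
#'   entries: `seed`; `paths` (`recording`, `annotation` -- when absent a
#'   session is simulated); `generator` (overrides passed to
#'   [generator_config()]); `detector` ([detector_config()] overrides plus
#'   `grid`, `calibrate`); `segmentation` ([segmentation_params()]
#'   overrides); `metrics` (`session_minutes`, `log_base`,
#'   `interval_convention`); `baseline_segment` (two numbers, seconds).
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return A list with `recording`, `annotation`, `baseline`,
#'   `calibration` (or `NULL`), `spikes`, `seizures`, `metrics`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  config_hash <- rlang::hash(config)

  if (!is.null(config$paths$recording)) {
    if (!file.exists(config$paths$recording))
      abort(paste0("recording file not found: ", config$paths$recording))
    recording <- read_recording(config$paths$recording)
    annotation <- if (!is.null(config$paths$annotation)) {
      if (!file.exists(config$paths$annotation))
        abort(paste0("annotation file not found: ", config$paths$annotation))
      read_annotations(config$paths$annotation)
    } else NULL
    gen_cfg <- NULL
  } else {
    gen_args <- config$generator %||% list()
    if (!is.null(gen_args$seizure_schedule))
      gen_args$seizure_schedule <- tibble::as_tibble(gen_args$seizure_schedule)
    if (!is.null(gen_args$hfs_epochs))
      gen_args$hfs_epochs <- tibble::as_tibble(gen_args$hfs_epochs)
    gen_args$seed <- seed
    gen_cfg <- do.call(generator_config, gen_args)
    sim <- generate_session(gen_cfg)
    recording <- sim$recording
    annotation <- sim$annotation
  }

  seg_base <- config$baseline_segment %||%
    c(0, gen_cfg$baseline_quiet_s %||% 60)
  baseline_ca3 <- estimate_baseline(recording, seg_base, channel = "CA3")
  baseline_mcx <- estimate_baseline(recording, seg_base, channel = "MCX")

  det_args <- config$detector %||% list()
  grid <- det_args$grid %||% c(4, 9, 16, 25, 36, 49)
  do_cal <- det_args$calibrate %||% TRUE
  det_cfg <- do.call(detector_config,
                     det_args[intersect(names(det_args),
                                        names(formals(detector_config)))])

  seg_params <- do.call(segmentation_params, config$segmentation %||% list())
  ca3_iv <- segment_seizures(recording, baseline_ca3, seg_params, channel = "CA3")
  mcx_iv <- segment_seizures(recording, baseline_mcx, seg_params, channel = "MCX")

  stages <- if (!is.null(annotation)) {
    st <- annotation_events(annotation, "stage")
    tibble::tibble(time_s = st$onset_s, stage = st$label)
  } else tibble::tibble(time_s = numeric(), stage = character())
  seizures <- classify_seizures(ca3_iv, mcx_iv, stages)
  seizures <- detect_status_epilepticus(seizures, gap_s = seg_params$merge_gap_s)

  excl <- exclusion_intervals(annotation = annotation, seizures = ca3_iv)
  calibration <- NULL
  if (do_cal && !is.null(annotation)) {
    truth_spikes <- annotation_events(annotation, "spike")
    if (nrow(truth_spikes) < 5)
      abort("calibration requested but the annotation has fewer than 5 true spikes")
    calibration <- calibrate_threshold(
      recording, baseline_ca3, truth_spikes, grid = grid, config = det_cfg,
      channel = "CA3", exclude = excl)
    det_cfg$C <- calibration$chosen_C
  }
  spikes <- detect_spikes(recording, baseline_ca3, det_cfg,
                          channel = "CA3", exclude = excl)

  met_args <- config$metrics %||% list()
  metrics <- compute_session_metrics(
    seizures, spikes, annotation %||% minimal_annotation(),
    session_minutes = met_args$session_minutes %||% 90,
    session_duration = nrow(recording) / sampling_rate(recording),
    log_base = met_args$log_base %||% 10,
    interval_convention = met_args$interval_convention %||% "onset")

  out <- list(recording = recording, annotation = annotation,
              baseline = dplyr::bind_rows(baseline_ca3, baseline_mcx),
              calibration = calibration, spikes = spikes,
              seizures = seizures, metrics = metrics)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(spikes, file.path(out_dir, "spikes.csv"))
    write_events(seizures, file.path(out_dir, "seizures.csv"))
    readr::write_csv(metrics[, setdiff(names(metrics), "inter_focal_log")],
                     file.path(out_dir, "metrics.csv"), progress = FALSE)
    if (!is.null(annotation))
      write_annotations(annotation, file.path(out_dir, "annotation.csv"))
    if (!is.null(calibration))
      jsonlite::write_json(
        list(chosen_C = calibration$chosen_C,
             criterion_met = calibration$criterion_met,
             report = calibration$report, sweep = calibration$sweep),
        file.path(out_dir, "calibration.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(
      list(config_hash = config_hash, seed = seed,
           package = "seizr",
           version = as.character(utils::packageVersion("seizr")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "log.json"), auto_unbox = TRUE)
  }
  invisible(out)
}

minimal_annotation <- function() {
  new_annotation(tibble::tibble(
    event_type = "injection", channel = NA_character_,
    onset_s = 0, offset_s = NA_real_, label = NA_character_))
}
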