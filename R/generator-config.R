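#' Configuration for the synthetic EEG session generator
#'
#' Bundles every knob of the two-channel synthetic rodent-EEG generator:
#' the stationary Gaussian (or pink) background, transient interictal
#' spikes, scheduled seizures with an amplitude/frequency ramp, delayed
#' generalization to the motor-cortex channel, status epilepticus, and
#' optional high-frequency-stimulation (HFS) artifact epochs.
#'
#' @param sampling_rate Sampling rate in Hz. Default 512.
#' @param session_duration Session length in seconds. Default 5400 (90 min,
#'   the length of one post-injection monitoring session).
#' @param baseline_mu Mean of the background EEG amplitude, in microvolts.
#' @param baseline_sigma Standard deviation of the background EEG amplitude,
#'   in microvolts. May be 0 for a degenerate constant signal.
#' @param noise_kind `"white"` (Gaussian white noise, matching the detector's
#'   distributional assumption) or `"pink"` (1/f-filtered noise for
#'   robustness checks).
#' @param spike_rate Interictal spike rate in events per minute (CA3 channel).
#' @param spike_duration_range Two-element numeric, spike duration bounds in
#'   milliseconds (full width at half amplitude). Default `c(20, 70)`.
#' @param spike_amplitude_factor Minimum spike peak deviation as a multiple of
#'   the background amplitude envelope (the 95% envelope
#'   `qnorm(0.975) * baseline_sigma`). Default 2.
#' @param seizure_schedule Data frame with columns `onset_s`, `duration_s`,
#'   `class` (`"focal"` or `"generalized"`), `stage` (Racine `"I"`..`"V"`),
#'   and optionally `generalization_delay_s` (seconds, generalized events
#'   only; default 2). Onsets refer to the instant the ramping spike train
#'   crosses twice the background envelope (the electrographic seizure-start
#'   definition); a sub-threshold build-up is rendered just before each onset.
#' @param seizure_amplitude_factor Sustained ictal spike amplitude as a
#'   multiple of the background envelope. Default 3.
#' @param seizure_ramp_s Total duration in seconds of the linear
#'   amplitude/frequency ramp at seizure start. Default 8.
#' @param ictal_rate_range Two-element numeric, ictal spike-train rate ramp in
#'   Hz (start to sustained). Default `c(1, 8)`.
#' @param se_flag If `TRUE` and no schedule is supplied, schedules a single
#'   generalized stage-V seizure lasting more than 30 minutes (status
#'   epilepticus).
#' @param hfs_epochs Data frame with columns `start_s`, `end_s`: epochs during
#'   which a 125 Hz square-wave stimulation artifact is added to the CA3
#'   channel.
#' @param baseline_quiet_s Initial stretch of the session kept free of
#'   scheduled events, available for baseline estimation. Default 60.
#' @param injection_times Numeric vector of injection times in seconds.
#'   Default 0 (time origin at injection; seizure latency is then simply the
#'   first seizure onset).
#' @param seed Integer seed; a fixed seed makes the generated session
#'   reproducible bit for bit.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_session()], [generate_baseline_noise()]
#' @export
generator_config <- function(sampling_rate = 512,
                             session_duration = 5400,
                             baseline_mu = 0,
                             baseline_sigma = 50,
                             noise_kind = c("white", "pink"),
                             spike_rate = 6,
                             spike_duration_range = c(20, 70),
                             spike_amplitude_factor = 2,
                             seizure_schedule = NULL,
                             seizure_amplitude_factor = 3,
                             seizure_ramp_s = 8,
                             ictal_rate_range = c(1, 8),
                             se_flag = FALSE,
                             hfs_epochs = NULL,
                             baseline_quiet_s = 60,
                             injection_times = 0,
                             seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort("`sampling_rate` must be a positive number (Hz)")
  if (!is.numeric(session_duration) || session_duration <= 0)
    abort("`session_duration` must be a positive number (seconds)")
  if (baseline_sigma < 0) abort("`baseline_sigma` must be >= 0")
  if (spike_rate < 0) abort("`spike_rate` must be >= 0")
  if (length(spike_duration_range) != 2 ||
      spike_duration_range[1] <= 0 ||
      spike_duration_range[1] > spike_duration_range[2] ||
      spike_duration_range[2] / 1000 >= session_duration)
    abort("`spike_duration_range` must be increasing, positive, and shorter than the session")
  if (spike_amplitude_factor < 1) abort("`spike_amplitude_factor` must be >= 1")
  if (seizure_amplitude_factor <= 1) abort("`seizure_amplitude_factor` must be > 1")

  if (se_flag && (is.null(seizure_schedule) || nrow(seizure_schedule) == 0)) {
    seizure_schedule <- tibble::tibble(
      onset_s = min(600, session_duration * 0.2),
      duration_s = 1900,
      class = "generalized", stage = "V",
      generalization_delay_s = 5
    )
  }
  seizure_schedule <- validate_schedule(seizure_schedule, session_duration,
                                        seizure_ramp_s, seizure_amplitude_factor)
  hfs_epochs <- validate_epochs(hfs_epochs, session_duration)

  structure(
    list(
      sampling_rate = sampling_rate,
      session_duration = session_duration,
      baseline_mu = baseline_mu,
      baseline_sigma = baseline_sigma,
      noise_kind = noise_kind,
      spike_rate = spike_rate,
      spike_duration_range = spike_duration_range,
      spike_amplitude_factor = spike_amplitude_factor,
      seizure_schedule = seizure_schedule,
      seizure_amplitude_factor = seizure_amplitude_factor,
      seizure_ramp_s = seizure_ramp_s,
      ictal_rate_range = ictal_rate_range,
      se_flag = se_flag,
      hfs_epochs = hfs_epochs,
      baseline_quiet_s = baseline_quiet_s,
      injection_times = injection_times,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# The background amplitude envelope the generator scales events against:
# the theoretical 95% envelope of the Gaussian background.
config_envelope <- function(config) qnorm(0.975) * config$baseline_sigma

validate_schedule <- function(schedule, session_duration, ramp_s, amp_factor) {
  if (is.null(schedule) || nrow(as.data.frame(schedule)) == 0) {
    return(tibble::tibble(onset_s = numeric(), duration_s = numeric(),
                          class = character(), stage = character(),
                          generalization_delay_s = numeric()))
  }
  schedule <- tibble::as_tibble(schedule)
  needed <- c("onset_s", "duration_s", "class", "stage")
  missing <- setdiff(needed, names(schedule))
  if (length(missing))
    abort(paste0("seizure_schedule lacks column(s): ", paste(missing, collapse = ", ")))
  if (!"generalization_delay_s" %in% names(schedule))
    schedule$generalization_delay_s <- 2
  schedule$generalization_delay_s[is.na(schedule$generalization_delay_s)] <- 2
  if (!all(schedule$class %in% c("focal", "generalized")))
    abort("seizure class must be 'focal' or 'generalized'")
  st <- stage_to_int(schedule$stage)
  schedule$stage <- stage_to_roman(st)
  bad_focal <- schedule$class == "focal" & st > 2
  bad_gen <- schedule$class == "generalized" & st < 3
  if (any(bad_focal | bad_gen))
    abort("stage/class mismatch: focal seizures carry stage I-II, generalized stage III-V")
  if (any(schedule$duration_s <= 0)) abort("seizure duration_s must be > 0")
  # pre-roll: the sub-threshold build-up rendered before the annotated onset
  pre <- ramp_s * min(1, 1 / (amp_factor - 1))
  if (any(schedule$onset_s - pre < 0 |
          schedule$onset_s + schedule$duration_s > session_duration))
    abort("scheduled seizures (including ramp pre-roll) must lie inside the session")
  schedule <- dplyr::arrange(schedule, .data$onset_s)
  if (nrow(schedule) > 1) {
    gap <- schedule$onset_s[-1] - pre -
      (schedule$onset_s[-nrow(schedule)] + schedule$duration_s[-nrow(schedule)])
    if (any(gap <= 0)) abort("scheduled seizures overlap (ramp pre-roll included)")
  }
  schedule
}

validate_epochs <- function(epochs, session_duration) {
  if (is.null(epochs) || nrow(as.data.frame(epochs)) == 0)
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  epochs <- tibble::as_tibble(epochs)
  if (!all(c("start_s", "end_s") %in% names(epochs)))
    abort("hfs_epochs needs columns start_s, end_s")
  if (any(epochs$start_s >= epochs$end_s) ||
      any(epochs$start_s < 0 | epochs$end_s > session_duration))
    abort("hfs_epochs must be well-ordered intervals inside the session")
  dplyr::arrange(epochs, .data$start_s)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %g Hz, %.0f s session; background %s(mu=%g, sigma=%g) uV\n",
              x$sampling_rate, x$session_duration, x$noise_kind,
              x$baseline_mu, x$baseline_sigma))
  cat(sprintf("  spikes: %g/min, %g-%g ms, >= %gx envelope\n",
              x$spike_rate, x$spike_duration_range[1], x$spike_duration_range[2],
              x$spike_amplitude_factor))
  cat(sprintf("  seizures scheduled: %d; HFS epochs: %d; seed %d\n",
              nrow(x$seizure_schedule), nrow(x$hfs_epochs), x$seed))
  invisible(x)
}
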