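#' Generate stationary background EEG noise
#'
#' Draws one channel of stationary background activity whose amplitude
#' distribution matches the Gaussian baseline model assumed by the spike
#' detector: empirical mean converges to `baseline_mu` and standard
#' deviation to `baseline_sigma` as the duration grows. Pink noise
#' (`noise_kind = "pink"`) is produced by 1/f shaping of white noise in the
#' frequency domain and rescaled to the same first two moments.
#'
#' @param config A [generator_config()].
#' @param duration Duration in seconds (> 0).
#' @param seed Integer seed, defaulting to `config$seed`; pass `NULL` to use
#'   the current RNG state.
#' @return Numeric vector of `round(duration * sampling_rate)` samples (uV).
#' @export
generate_baseline_noise <- function(config, duration, seed = config$seed) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    abort("`duration` must be a single positive number of seconds")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * config$sampling_rate)
  draw_noise(n, config$baseline_mu, config$baseline_sigma, config$noise_kind)
}

draw_noise <- function(n, mu, sigma, kind) {
  if (sigma == 0) return(rep(mu, n))
  if (kind == "white") return(rnorm(n, mu, sigma))
  # pink: shape white noise by 1/sqrt(f) in the frequency domain
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index, DC guarded
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  mu + sigma * (x - mean(x)) / sd(x)
}

#' Construct a single synthetic spike waveform
#'
#' Builds the biphasic sharp transient used for both interictal spikes and
#' ictal spike trains: a pointed triangular main lobe followed by a smaller
#' opposite-polarity undershoot (25% of the peak). The waveform's duration
#' convention is the clinical one for the 20-70 ms spike rule: full width at
#' half the peak amplitude equals `duration_ms` (within one sample period).
#' The rendered support is about three times that nominal duration.
#'
#' @param duration_ms Spike duration in milliseconds, measured as full width
#'   at half amplitude; must lie in (0, 200].
#' @param peak_amplitude Peak absolute deviation in microvolts (> 0).
#' @param polarity `+1` or `-1`; `-1` returns the exact negation of the
#'   `+1` waveform.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric waveform vector; `max(abs(.))` equals `peak_amplitude`
#'   and the attribute `"peak_index"` marks the apex sample.
#' @export
synth_spike_waveform <- function(duration_ms, peak_amplitude, polarity = 1,
                                 sampling_rate = 512) {
  if (!is.numeric(duration_ms) || duration_ms <= 0 || duration_ms > 200)
    abort("`duration_ms` must lie in (0, 200]")
  if (!is.numeric(peak_amplitude) || peak_amplitude <= 0)
    abort("`peak_amplitude` must be > 0")
  if (!polarity %in% c(-1, 1)) abort("`polarity` must be +1 or -1")
  d <- duration_ms / 1000
  k0 <- round(d * sampling_rate)                  # apex lands on a sample
  idx <- 0:(k0 + round(2 * d * sampling_rate))
  t <- (idx - k0) / sampling_rate                 # t = 0 at the apex
  main <- pmax(0, 1 - abs(t) / d)
  under <- -0.25 * pmax(0, 1 - abs(t - 1.5 * d) / (0.5 * d))
  w <- polarity * peak_amplitude * (main + under)
  structure(w, peak_index = k0 + 1L)
}

new_recording <- function(time_s, ca3, mcx, sampling_rate) {
  out <- tibble::tibble(time_s = time_s, CA3_uV = ca3, MCX_uV = mcx)
  class(out) <- c("eeg_recording", class(out))
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  fs <- attr(x, "sampling_rate")
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), channels: %s\n",
              nrow(x), fs, nrow(x) / fs,
              paste(setdiff(names(x), "time_s"), collapse = ", ")))
  NextMethod()
}

#' Sampling rate of a recording
#' @param recording An `eeg_recording`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(recording) {
  fs <- attr(recording, "sampling_rate")
  if (is.null(fs)) {
    dt <- diff(recording$time_s[1:2])
    fs <- 1 / dt
  }
  fs
}

new_annotation <- function(df, session_duration = NA_real_) {
  df <- tibble::as_tibble(df)
  df <- df[order(df$onset_s, method = "radix"), ]
  class(df) <- c("session_annotation", class(df))
  attr(df, "session_duration") <- session_duration
  df
}

#' Filter a session annotation by event type
#'
#' @param annotation A session annotation tibble (columns `event_type`,
#'   `channel`, `onset_s`, `offset_s`, `label`).
#' @param type One of `"spike"`, `"seizure"`, `"stage"`, `"injection"`,
#'   `"hfs"`.
#' @return The matching rows, as a tibble.
#' @export
annotation_events <- function(annotation, type) {
  dplyr::filter(tibble::as_tibble(annotation), .data$event_type == type)
}

# add a rendered waveform into signal x at a given apex time (seconds)
add_waveform_at <- function(x, w, apex_s, fs) {
  pk <- attr(w, "peak_index")
  i0 <- round(apex_s * fs) + 1L - (pk - 1L)
  j <- seq_along(w) + i0 - 1L
  keep <- j >= 1L & j <= length(x)
  x[j[keep]] <- x[j[keep]] + w[keep]
  x
}

# Ictal spike-train times and per-spike amplitudes for one seizure.
# The ramp runs from t_start (rate r0, amplitude 1x envelope) to
# t_start + ramp_s (sustained rate r1, amplitude F x envelope); the
# annotated onset sits where the amplitude ramp crosses 2x the envelope.
ictal_train <- function(t_start, t_end, ramp_s, rate_range, envelope, amp_factor) {
  times <- numeric(0)
  t <- t_start
  while (t < t_end) {
    u <- min(1, max(0, (t - t_start) / ramp_s))
    rate <- rate_range[1] + (rate_range[2] - rate_range[1]) * u
    times <- c(times, t)
    t <- t + (1 / rate) * runif(1, 0.85, 1.15)
  }
  u <- pmin(1, pmax(0, (times - t_start) / ramp_s))
  amp <- envelope * (1 + (amp_factor - 1) * u) * runif(length(times), 0.92, 1.08)
  list(times = times, amp = amp)
}

#' Generate a complete synthetic two-channel EEG session
#'
#' Renders a CA3 (injection-site) and MCX (contralateral motor cortex)
#' channel: stationary background noise, Poisson-scheduled interictal spikes
#' on CA3, scheduled seizures as spike trains whose rate and amplitude ramp
#' up at onset, delayed involvement of the MCX channel for generalized
#' seizures, and optional 125 Hz square-wave stimulation-artifact epochs.
#' Every injected event is listed in the returned ground-truth annotation.
#'
#' @param config A [generator_config()].
#' @return A list with elements `recording` (an `eeg_recording` tibble:
#'   `time_s`, `CA3_uV`, `MCX_uV`) and `annotation` (a `session_annotation`
#'   tibble: `event_type`, `channel`, `onset_s`, `offset_s`, `label`).
#'   Spike rows carry their true interval (full width at half amplitude)
#'   and, in `label`, the injected clean peak amplitude in microvolts;
#'   seizure rows appear once per involved channel with `label` equal to the
#'   seizure class; `stage` rows mark the behavioural Racine stage at each
#'   seizure onset.
#' @export
generate_session <- function(config) {
  if (!inherits(config, "generator_config"))
    abort("`config` must be a generator_config()")
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$session_duration * fs)
  time_s <- (seq_len(n) - 1) / fs
  envelope <- config_envelope(config)

  ca3 <- draw_noise(n, config$baseline_mu, config$baseline_sigma, config$noise_kind)
  mcx <- draw_noise(n, config$baseline_mu, config$baseline_sigma, config$noise_kind)

  ann <- list()
  sched <- config$seizure_schedule
  pre_s <- config$seizure_ramp_s * min(1, 1 / (config$seizure_amplitude_factor - 1))

  if (nrow(sched) > 0) {
    for (i in seq_len(nrow(sched))) {
      ev <- sched[i, ]
      t0 <- ev$onset_s
      t_end <- t0 + ev$duration_s
      tr <- ictal_train(t0 - pre_s, t_end, config$seizure_ramp_s,
                        config$ictal_rate_range, envelope,
                        config$seizure_amplitude_factor)
      pol <- sample(c(-1, 1), 1)
      for (k in seq_along(tr$times)) {
        w <- synth_spike_waveform(runif(1, 30, 60), tr$amp[k], pol, fs)
        ca3 <- add_waveform_at(ca3, w, tr$times[k], fs)
      }
      ann[[length(ann) + 1]] <- tibble::tibble(
        event_type = "seizure", channel = "CA3",
        onset_s = t0, offset_s = t_end, label = ev$class)
      if (ev$class == "generalized") {
        delay <- ev$generalization_delay_s
        trm <- ictal_train(t0 - pre_s + delay, t_end, config$seizure_ramp_s,
                           config$ictal_rate_range, envelope,
                           config$seizure_amplitude_factor)
        keep <- trm$times < t_end
        for (k in which(keep)) {
          w <- synth_spike_waveform(runif(1, 30, 60), trm$amp[k], pol, fs)
          mcx <- add_waveform_at(mcx, w, trm$times[k], fs)
        }
        ann[[length(ann) + 1]] <- tibble::tibble(
          event_type = "seizure", channel = "MCX",
          onset_s = t0 + delay, offset_s = t_end, label = ev$class)
      }
      ann[[length(ann) + 1]] <- tibble::tibble(
        event_type = "stage", channel = NA_character_,
        onset_s = t0, offset_s = NA_real_, label = ev$stage)
    }
  }

  # interictal spikes on CA3: homogeneous Poisson, thinned away from
  # seizures (ramp pre-roll included), HFS epochs, the baseline-estimation
  # window, and each other (>= 250 ms separation)
  if (config$spike_rate > 0) {
    n_spk <- rpois(1, config$spike_rate * config$session_duration / 60)
    cand <- sort(runif(n_spk, 0, config$session_duration))
    max_d <- config$spike_duration_range[2] / 1000
    ok <- cand > max(config$baseline_quiet_s, max_d * 2) &
      cand < config$session_duration - max_d * 2
    if (nrow(sched) > 0) {
      for (i in seq_len(nrow(sched)))
        ok <- ok & (cand < sched$onset_s[i] - pre_s - 1 |
                      cand > sched$onset_s[i] + sched$duration_s[i] + 1)
    }
    if (nrow(config$hfs_epochs) > 0) {
      for (i in seq_len(nrow(config$hfs_epochs)))
        ok <- ok & (cand < config$hfs_epochs$start_s[i] - 0.5 |
                      cand > config$hfs_epochs$end_s[i] + 0.5)
    }
    cand <- cand[ok]
    if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) >= 0.25)]
    if (length(cand) > 0) {
      dur_ms <- runif(length(cand), config$spike_duration_range[1],
                      config$spike_duration_range[2])
      amp <- envelope * config$spike_amplitude_factor * runif(length(cand), 1.1, 1.6)
      pol <- sample(c(-1, 1), length(cand), replace = TRUE)
      for (k in seq_along(cand)) {
        w <- synth_spike_waveform(dur_ms[k], amp[k], pol[k], fs)
        ca3 <- add_waveform_at(ca3, w, cand[k], fs)
      }
      ann[[length(ann) + 1]] <- tibble::tibble(
        event_type = "spike", channel = "CA3",
        onset_s = cand - dur_ms / 2000, offset_s = cand + dur_ms / 2000,
        label = sprintf("%.3f", amp))
    }
  }

  if (nrow(config$hfs_epochs) > 0) {
    for (i in seq_len(nrow(config$hfs_epochs))) {
      i0 <- max(1L, round(config$hfs_epochs$start_s[i] * fs) + 1L)
      i1 <- min(n, round(config$hfs_epochs$end_s[i] * fs))
      tt <- time_s[i0:i1]
      ca3[i0:i1] <- ca3[i0:i1] +
        3 * envelope * sign(sin(2 * pi * 125 * tt) + 1e-12)
      ann[[length(ann) + 1]] <- tibble::tibble(
        event_type = "hfs", channel = "CA3",
        onset_s = config$hfs_epochs$start_s[i],
        offset_s = config$hfs_epochs$end_s[i], label = NA_character_)
    }
  }

  ann[[length(ann) + 1]] <- tibble::tibble(
    event_type = "injection", channel = NA_character_,
    onset_s = config$injection_times, offset_s = NA_real_,
    label = NA_character_)

  list(
    recording = new_recording(time_s, ca3, mcx, fs),
    annotation = new_annotation(dplyr::bind_rows(ann), config$session_duration)
  )
}
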