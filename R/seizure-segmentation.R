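#' Segmentation parameters
#'
#' Tunables of the rule-based electrographic seizure segmenter. A sliding
#' window qualifies as ictal when it contains spike-train activity (at
#' least `min_spikes` deviations beyond `spike_factor` times the background
#' envelope) and its energy exceeds the baseline: with
#' `baseline_ref = "rms"` (default) window RMS must reach `onset_factor`
#' times the baseline RMS (ictal activity is oscillatory, so "twice the
#' baseline" is read on the RMS scale); with `baseline_ref = "envelope"`
#' the window's peak deviation must reach `onset_factor` times the
#' background envelope instead. The seizure onset is the start of the first
#' stretch of qualifying windows sustained for `sustain_s`; the offset is
#' the first subsequent time the RMS stays below `offset_factor` times
#' baseline for `offset_sustain_s` (hysteresis). Events separated by less
#' than `merge_gap_s` are merged.
#'
#' @param window_s Sliding window length (s). Default 2.
#' @param hop_s Window hop (s). Default 0.25.
#' @param sustain_s Minimum sustained qualifying time at onset (s). Default 2.
#' @param min_spikes Minimum supra-threshold spikes per window. Default 3.
#' @param spike_factor Spike threshold in background-envelope units. Default 2.
#' @param onset_factor Onset energy factor. Default 2.
#' @param offset_factor Offset (hysteresis) factor. Default 1.5.
#' @param offset_sustain_s Quiet time ending an event (s). Default 5.
#' @param merge_gap_s Events closer than this are merged (s). Default 10.
#' @param baseline_ref `"rms"` or `"envelope"` (see above).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(window_s = 2, hop_s = 0.25, sustain_s = 2,
                                min_spikes = 3, spike_factor = 2,
                                onset_factor = 2, offset_factor = 1.5,
                                offset_sustain_s = 5, merge_gap_s = 10,
                                baseline_ref = c("rms", "envelope")) {
  baseline_ref <- match.arg(baseline_ref)
  if (window_s <= 0 || hop_s <= 0 || hop_s > window_s)
    abort("need 0 < hop_s <= window_s")
  if (offset_factor >= onset_factor)
    abort("`offset_factor` must be below `onset_factor` (hysteresis)")
  structure(list(window_s = window_s, hop_s = hop_s, sustain_s = sustain_s,
                 min_spikes = min_spikes, spike_factor = spike_factor,
                 onset_factor = onset_factor, offset_factor = offset_factor,
                 offset_sustain_s = offset_sustain_s, merge_gap_s = merge_gap_s,
                 baseline_ref = baseline_ref),
            class = "segmentation_params")
}

# per-window statistics at hop resolution: RMS of (x - mu), peak |x - mu|,
# and count of supra-threshold spike-run starts in each window
window_stats <- function(x, baseline, params, fs) {
  W <- round(params$window_s * fs)
  H <- round(params$hop_s * fs)
  if (W > length(x)) abort("window longer than signal")
  d <- x - baseline$mu
  starts <- seq(1L, length(x) - W + 1L, by = H)
  cs2 <- cumsum(c(0, d^2))
  rms <- sqrt((cs2[starts + W] - cs2[starts]) / W)

  b <- abs(d) >= params$spike_factor * baseline$background_uV
  r <- rle(b)
  ends <- cumsum(r$lengths)
  run_starts <- (ends - r$lengths + 1L)[r$values]
  csr <- cumsum(c(0, tabulate(run_starts, nbins = length(x))))
  n_spk <- csr[pmin(length(x), starts + W - 1L) + 1L] - csr[starts]

  pk <- vapply(seq_along(starts),
               function(i) max(abs(d[starts[i]:(starts[i] + W - 1L)])),
               numeric(1))
  tibble::tibble(t = (starts - 1L) / fs, rms = rms, peak = pk, n_spikes = n_spk)
}

window_qualifies <- function(ws, baseline, params) {
  base_rms <- sqrt(baseline$sigma2)
  energy_ok <- if (params$baseline_ref == "rms") {
    ws$rms >= params$onset_factor * base_rms
  } else {
    ws$peak >= params$onset_factor * baseline$background_uV
  }
  energy_ok & ws$n_spikes >= params$min_spikes
}

#' Segment electrographic seizures on one channel
#'
#' Applies the windowed onset/offset rules of [segmentation_params()] to a
#' channel and returns the detected ictal intervals, merged across gaps
#' shorter than `merge_gap_s`.
#'
#' @inheritParams detect_spikes
#' @param params A [segmentation_params()].
#' @return Tibble with `onset_s`, `offset_s`, `duration_s`, sorted and
#'   non-overlapping.
#' @export
segment_seizures <- function(signal, baseline, params = segmentation_params(),
                             channel = NULL, sampling_rate = NULL) {
  s <- resolve_signal(signal, channel %||% baseline$channel, sampling_rate)
  ws <- window_stats(s$x, baseline, params, s$fs)
  q <- window_qualifies(ws, baseline, params)
  quiet <- ws$rms < params$offset_factor * sqrt(baseline$sigma2)
  n_sus <- max(1L, ceiling(params$sustain_s / params$hop_s))
  n_off <- max(1L, ceiling(params$offset_sustain_s / params$hop_s))
  dur_total <- length(s$x) / s$fs

  events <- list()
  k <- 1L
  nW <- length(q)
  while (k <= nW - n_sus + 1L) {
    if (all(q[k:(k + n_sus - 1L)])) {
      onset <- ws$t[k]
      # scan forward for a sustained quiet stretch
      j <- k + n_sus
      offset <- dur_total
      while (j <= nW - n_off + 1L) {
        if (all(quiet[j:(j + n_off - 1L)])) {
          offset <- ws$t[j]
          break
        }
        j <- j + 1L
      }
      events[[length(events) + 1L]] <- c(onset, offset)
      # resume after the event ends
      k <- if (offset >= dur_total) nW + 1L else j + n_off
    } else {
      k <- k + 1L
    }
  }
  out <- if (length(events)) {
    m <- do.call(rbind, events)
    tibble::tibble(onset_s = m[, 1], offset_s = m[, 2])
  } else {
    tibble::tibble(onset_s = numeric(), offset_s = numeric())
  }
  out <- merge_intervals(out, params$merge_gap_s)
  out$duration_s <- out$offset_s - out$onset_s
  out
}

# merge sorted intervals whose gap is below gap_s
merge_intervals <- function(iv, gap_s) {
  if (nrow(iv) <= 1) return(iv)
  iv <- dplyr::arrange(iv, .data$onset_s)
  on <- iv$onset_s; off <- iv$offset_s
  keep_on <- on[1]; keep_off <- off[1]
  res <- list()
  for (i in seq_along(on)[-1]) {
    if (on[i] - keep_off < gap_s) {
      keep_off <- max(keep_off, off[i])
    } else {
      res[[length(res) + 1]] <- c(keep_on, keep_off)
      keep_on <- on[i]; keep_off <- off[i]
    }
  }
  res[[length(res) + 1]] <- c(keep_on, keep_off)
  m <- do.call(rbind, res)
  tibble::tibble(onset_s = m[, 1], offset_s = m[, 2])
}

#' Classify seizures as focal or generalized
#'
#' Combines the two channels with the behavioural Racine-stage annotations:
#' a CA3 interval that overlaps a motor-cortex (MCX) interval *and* carries
#' stage III-V is generalized; a CA3-only interval with stage I-II is
#' focal; any conflicting combination (e.g. CA3-only with stage V) is
#' returned flagged `"unclassified"`, never silently coerced. Synchrony is
#' any temporal overlap -- the MCX channel typically joins with a delay, so
#' no onset alignment is required.
#'
#' @param ca3_intervals,mcx_intervals Tibbles of per-channel ictal intervals
#'   (`onset_s`, `offset_s`), e.g. from [segment_seizures()].
#' @param stages Tibble of behavioural stage annotations with columns
#'   `time_s` (or `onset_s`) and `stage` (Racine `"I"`..`"V"`); every CA3
#'   interval must carry at least one stage record within
#'   `[onset - stage_lookback_s, offset)`.
#' @param stage_lookback_s Stage records may precede the estimated
#'   electrographic onset by up to this many seconds and still be assigned
#'   to the interval (segmentation onsets carry a small estimation error).
#'   Default 5.
#' @return Tibble of class `seizure_events`: `onset_s`, `offset_s`,
#'   `duration_s`, `class` (`"focal"`, `"generalized"`, `"unclassified"`),
#'   `stage`, `channels`, `mcx_onset_s`, `is_se` (initialized `FALSE`).
#' @export
classify_seizures <- function(ca3_intervals, mcx_intervals, stages,
                              stage_lookback_s = 5) {
  ca3 <- dplyr::arrange(tibble::as_tibble(ca3_intervals), .data$onset_s)
  mcx <- tibble::as_tibble(mcx_intervals)
  st <- tibble::as_tibble(stages)
  if (!"time_s" %in% names(st)) st$time_s <- st$onset_s
  st$stage_int <- stage_to_int(st$stage)

  n <- nrow(ca3)
  cls <- character(n); stg <- integer(n); mcx_on <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    on <- ca3$onset_s[i]; off <- ca3$offset_s[i]
    in_iv <- st$time_s >= on - stage_lookback_s & st$time_s < off
    if (!any(in_iv))
      abort(sprintf(
        "no Racine stage annotation overlaps seizure interval [%.1f, %.1f) s",
        on, off))
    stg[i] <- max(st$stage_int[in_iv])
    ovl <- which(mcx$onset_s < off & mcx$offset_s > on)
    sync <- length(ovl) > 0
    if (sync) mcx_on[i] <- min(mcx$onset_s[ovl])
    cls[i] <- if (sync && stg[i] >= 3) "generalized"
      else if (!sync && stg[i] <= 2) "focal"
      else "unclassified"
  }
  out <- tibble::tibble(
    onset_s = ca3$onset_s, offset_s = ca3$offset_s,
    duration_s = ca3$offset_s - ca3$onset_s,
    class = cls, stage = stage_to_roman(stg),
    channels = ifelse(is.na(mcx_on), "CA3", "CA3+MCX"),
    mcx_onset_s = mcx_on, is_se = FALSE)
  class(out) <- c("seizure_events", class(out))
  out
}

#' Flag status epilepticus
#'
#' Status epilepticus (SE) is continuous electrographic seizure activity
#' lasting more than 30 minutes. Events separated by less than `gap_s`
#' form a chain (the segmenter's merge rule); every member of a chain whose
#' total span exceeds 1800 s is flagged `is_se = TRUE`.
#'
#' @param events A `seizure_events` tibble (sorted by onset).
#' @param gap_s Chain gap in seconds. Default 10.
#' @param threshold_s SE duration threshold in seconds. Default 1800.
#' @return The events with `is_se` set.
#' @export
detect_status_epilepticus <- function(events, gap_s = 10, threshold_s = 1800) {
  ev <- dplyr::arrange(tibble::as_tibble(events), .data$onset_s)
  if (!"is_se" %in% names(ev)) ev$is_se <- FALSE
  if (nrow(ev) == 0) return(events)
  gap_prev <- c(Inf, ev$onset_s[-1] - ev$offset_s[-nrow(ev)])
  chain <- cumsum(gap_prev >= gap_s)
  spans <- tapply(ev$offset_s, chain, max) - tapply(ev$onset_s, chain, min)
  ev$is_se <- as.vector(spans[as.character(chain)] > threshold_s)
  class(ev) <- unique(c(class(events)[1], class(ev)))
  ev
}

#' Simulate the responsive stimulation trigger
#'
#' Replays the seizure-onset rule causally: window statistics are evaluated
#' as each window completes, and a trigger fires at the moment the
#' sustained onset criterion is first confirmed (no future samples are
#' used). Stimulation persists until the offset rule is confirmed -- the
#' first causally observed stretch of `offset_sustain_s` below the
#' hysteresis level. When ground-truth seizures are supplied, each
#' trigger's latency relative to the matching true onset is reported.
#'
#' @inheritParams segment_seizures
#' @param truth Optional tibble of true seizure intervals (`onset_s`,
#'   `offset_s`) for latency computation.
#' @return Tibble with one row per trigger: `trigger_s`, `stop_s`, and if
#'   truth was given `true_onset_s` and `latency_s`.
#' @export
simulate_responsive_trigger <- function(signal, baseline,
                                        params = segmentation_params(),
                                        channel = NULL, sampling_rate = NULL,
                                        truth = NULL) {
  s <- resolve_signal(signal, channel %||% baseline$channel, sampling_rate)
  ws <- window_stats(s$x, baseline, params, s$fs)
  q <- window_qualifies(ws, baseline, params)
  quiet <- ws$rms < params$offset_factor * sqrt(baseline$sigma2)
  n_sus <- max(1L, ceiling(params$sustain_s / params$hop_s))
  n_off <- max(1L, ceiling(params$offset_sustain_s / params$hop_s))
  # window k's statistic is causally available at ws$t[k] + window_s
  avail <- ws$t + params$window_s

  trig <- list()
  k <- n_sus
  nW <- length(q)
  while (k <= nW) {
    if (all(q[(k - n_sus + 1L):k])) {
      t_on <- avail[k]
      j <- k + 1L
      t_stop <- length(s$x) / s$fs
      while (j + n_off - 1L <= nW) {
        if (all(quiet[j:(j + n_off - 1L)])) {
          t_stop <- avail[j + n_off - 1L]
          break
        }
        j <- j + 1L
      }
      trig[[length(trig) + 1L]] <- c(t_on, t_stop)
      k <- j + n_off
    } else {
      k <- k + 1L
    }
  }
  out <- if (length(trig)) {
    m <- do.call(rbind, trig)
    tibble::tibble(trigger_s = m[, 1], stop_s = m[, 2])
  } else {
    tibble::tibble(trigger_s = numeric(), stop_s = numeric())
  }
  if (!is.null(truth) && nrow(out) > 0) {
    tru <- dplyr::arrange(tibble::as_tibble(truth), .data$onset_s)
    out$true_onset_s <- purrr::map_dbl(out$trigger_s, function(tt) {
      ok <- which(tru$onset_s - params$window_s <= tt & tru$offset_s + params$window_s >= tt)
      if (length(ok)) tru$onset_s[ok[1]] else NA_real_
    })
    out$latency_s <- out$trigger_s - out$true_onset_s
  }
  out
}
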