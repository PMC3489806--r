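#' Detector configuration
#'
#' Parameters of the baseline-Gaussian interictal spike detector. A sample
#' is a spike candidate when its squared standardized deviation from the
#' baseline model, `z^2 = (x - mu)^2 / sigma^2`, exceeds the empirical
#' threshold constant `C` (so `sqrt(C)` is the threshold in baseline SD
#' units). Candidate runs are merged across short gaps, then kept only if
#' the event's duration -- full width at half its peak deviation -- falls in
#' the 20-70 ms spike band (with one sample period of discretization grace
#' at each edge) and its peak deviation reaches `amplitude_factor` times the
#' background amplitude envelope.
#'
#' @param C Dimensionless threshold on the squared standardized deviation
#'   (> 0). Default 16 (i.e. 4 baseline SDs).
#' @param min_duration,max_duration Spike duration band in ms. Defaults 20, 70.
#' @param amplitude_factor Minimum peak deviation as a multiple of the
#'   background amplitude envelope (>= 1). Default 2.
#' @param merge_gap Candidate runs closer than this (ms) are merged. Default 10.
#' @param refractory Events starting within this interval (ms) after a kept
#'   event's offset are suppressed. Default 50.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(C = 16, min_duration = 20, max_duration = 70,
                            amplitude_factor = 2, merge_gap = 10,
                            refractory = 50) {
  if (C <= 0) abort("`C` must be > 0")
  if (min_duration <= 0 || min_duration >= max_duration)
    abort("need 0 < min_duration < max_duration")
  if (amplitude_factor < 1) abort("`amplitude_factor` must be >= 1")
  if (merge_gap < 0 || refractory < 0) abort("merge_gap and refractory must be >= 0")
  structure(list(C = C, min_duration = min_duration, max_duration = max_duration,
                 amplitude_factor = amplitude_factor, merge_gap = merge_gap,
                 refractory = refractory),
            class = "detector_config")
}

# resolve a signal argument: numeric vector, or eeg_recording + channel
resolve_signal <- function(signal, channel = NULL, sampling_rate = NULL) {
  if (is.numeric(signal)) {
    if (is.null(sampling_rate)) abort("`sampling_rate` is required for a bare numeric signal")
    return(list(x = as.numeric(signal), fs = sampling_rate,
                channel = channel %||% "signal"))
  }
  if (inherits(signal, "eeg_recording") || is.data.frame(signal)) {
    channel <- channel %||% "CA3"
    col <- paste0(channel, "_uV")
    if (!col %in% names(signal))
      abort(paste0("channel column `", col, "` not found in recording (have: ",
                   paste(setdiff(names(signal), "time_s"), collapse = ", "), ")"))
    return(list(x = signal[[col]], fs = sampling_rate(signal), channel = channel))
  }
  abort("`signal` must be a numeric vector or an eeg_recording")
}

#' Estimate the Gaussian baseline model of a channel
#'
#' Fits the statistical null the spike detector scores against: the mean
#' `mu` and variance `sigma2` of the amplitude of a baseline (pre-injection)
#' EEG segment, plus the derived background amplitude envelope, defined as
#' the 95th percentile of `|x - mu|` over the segment (a robust envelope
#' that spike outliers barely move).
#'
#' @param signal An `eeg_recording` or a numeric vector.
#' @param segment Two-element numeric `c(start_s, end_s)` delimiting the
#'   baseline segment; must contain at least one second of data.
#' @param channel Channel name when `signal` is a recording. Default `"CA3"`.
#' @param sampling_rate Required when `signal` is a bare numeric vector.
#' @return A one-row tibble of class `baseline_model`: `channel`, `mu`,
#'   `sigma2`, `background_uV`, `segment_start`, `segment_end`, `n`.
#' @export
estimate_baseline <- function(signal, segment, channel = NULL,
                              sampling_rate = NULL) {
  s <- resolve_signal(signal, channel, sampling_rate)
  if (length(segment) != 2 || segment[1] >= segment[2])
    abort("`segment` must be c(start_s, end_s) with start < end")
  i0 <- max(1L, floor(segment[1] * s$fs) + 1L)
  i1 <- min(length(s$x), ceiling(segment[2] * s$fs))
  if (i1 - i0 + 1 < s$fs)
    abort("baseline segment must contain at least 1 s of data")
  xs <- s$x[i0:i1]
  mu <- mean(xs)
  sigma2 <- var(xs)
  if (sigma2 == 0)
    abort("baseline segment has zero variance; cannot form a Gaussian baseline model")
  out <- tibble::tibble(
    channel = s$channel, mu = mu, sigma2 = sigma2,
    background_uV = as.numeric(quantile(abs(xs - mu), 0.95)),
    segment_start = segment[1], segment_end = segment[2],
    n = length(xs))
  class(out) <- c("baseline_model", class(out))
  out
}

#' Score samples against the baseline model
#'
#' Returns the squared standardized deviation `z^2 = (x - mu)^2 / sigma^2`
#' for every sample. Under the Gaussian baseline density `f(x)`, `z^2` is a
#' strictly decreasing transform of `f(x)`, so thresholding `z^2` above `C`
#' is exactly equivalent to thresholding the density below a level: the
#' least-probable samples score highest.
#'
#' @inheritParams estimate_baseline
#' @param baseline A [estimate_baseline()] model.
#' @return Numeric vector of per-sample scores (dimensionless).
#' @export
score_samples <- function(signal, baseline, channel = NULL,
                          sampling_rate = NULL) {
  s <- resolve_signal(signal, channel %||% baseline$channel, sampling_rate)
  (s$x - baseline$mu)^2 / baseline$sigma2
}

# zero out scores inside exclusion intervals (tibble onset_s/offset_s or
# start_s/end_s); intervals are closed-open in seconds
mask_intervals <- function(z, intervals, fs) {
  if (is.null(intervals) || nrow(as.data.frame(intervals)) == 0) return(z)
  iv <- tibble::as_tibble(intervals)
  on <- iv$onset_s %||% iv$start_s
  off <- iv$offset_s %||% iv$end_s
  for (i in seq_along(on)) {
    i0 <- max(1L, floor(on[i] * fs) + 1L)
    i1 <- min(length(z), ceiling(off[i] * fs))
    if (i0 <= i1) z[i0:i1] <- 0
  }
  z
}

#' Detect interictal spikes
#'
#' Runs the baseline-Gaussian detector: samples scoring `z^2 > C` form
#' candidate runs; runs separated by less than `merge_gap` are merged; each
#' merged run becomes one event: its apex is the raw extremum nearest the
#' maximum of a 3-sample local mean of the absolute deviation (so a lone
#' noise excursion on a flank cannot masquerade as the peak); its
#' onset/offset are the first outward crossings of the smoothed trace
#' below half the apex deviation; and its duration -- full width at half
#' amplitude -- is the total time the smoothed trace spends above half
#' amplitude within 250 ms of the apex, which under noise is an unbiased
#' width estimate where either crossing statistic alone is not. Events
#' are kept when that
#' duration lies in the configured 20-70 ms band (one sample period of
#' grace per edge) and the peak deviation reaches
#' `amplitude_factor * background_uV`; events starting within the
#' refractory interval of the previous kept event are suppressed. Samples
#' inside `exclude` intervals (detected seizures, stimulation epochs --
#' interictal by definition) are ignored.
#'
#' @inheritParams score_samples
#' @param config A [detector_config()].
#' @param exclude Optional tibble of intervals (`onset_s`/`offset_s` or
#'   `start_s`/`end_s`) masked before scanning.
#' @return A tibble of class `spike_events`, sorted by onset: `channel`,
#'   `onset_s`, `offset_s`, `duration_ms`, `peak_uV` (signed peak
#'   deviation), `peak_score`.
#' @export
detect_spikes <- function(signal, baseline, config = detector_config(),
                          channel = NULL, sampling_rate = NULL,
                          exclude = NULL) {
  if (!inherits(config, "detector_config"))
    abort("`config` must be a detector_config()")
  s <- resolve_signal(signal, channel %||% baseline$channel, sampling_rate)
  fs <- s$fs
  if (length(s$x) < config$max_duration / 1000 * fs)
    abort("signal must cover at least max_duration")
  dev <- s$x - baseline$mu
  z <- dev^2 / baseline$sigma2
  z <- mask_intervals(z, exclude, fs)

  r <- rle(z > config$C)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  empty <- tibble::tibble(channel = character(), onset_s = numeric(),
                          offset_s = numeric(), duration_ms = numeric(),
                          peak_uV = numeric(), peak_score = numeric())
  class(empty) <- c("spike_events", class(empty))
  if (nrow(runs) == 0) return(empty)

  # merge runs across gaps shorter than merge_gap
  gap_max <- config$merge_gap / 1000 * fs
  if (nrow(runs) > 1) {
    gaps <- runs[-1, 1] - runs[-nrow(runs), 2] - 1L
    grp <- cumsum(c(1L, as.integer(gaps >= gap_max)))
    runs <- cbind(tapply(runs[, 1], grp, min), tapply(runs[, 2], grp, max))
  }

  half_max <- round(0.25 * fs) # cap half-amplitude expansion at 250 ms
  # 3-sample local mean of the absolute deviation over the whole signal:
  # a lone noise excursion on a flank must not masquerade as the peak
  a <- abs(dev)
  nfull <- length(a)
  sm <- (a + c(a[-1], a[nfull]) + c(a[1], a[-nfull])) / 3
  ev <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    ism <- seg[which.max(sm[seg])]
    cand <- max(1L, ism - 1L):min(length(dev), ism + 1L)
    ipk <- cand[which.max(abs(dev[cand]))]
    peak <- dev[ipk]
    half <- abs(peak) / 2
    # onset/offset: outward crossing of the smoothed trace below half the
    # apex deviation, sustained for two samples (one noisy dip must not
    # truncate the event)
    lo <- ipk; j <- ipk; gap <- 0L
    while (j > 1L && ipk - j < half_max) {
      j <- j - 1L
      if (sm[j] >= half) { lo <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap >= 2L) break }
    }
    hi <- ipk; j <- ipk; gap <- 0L
    while (j < length(dev) && j - ipk < half_max) {
      j <- j + 1L
      if (sm[j] >= half) { hi <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap >= 2L) break }
    }
    # duration for the band filter: total time the smoothed trace spends
    # above half amplitude near the apex (unbiased under noise, unlike
    # either crossing statistic alone)
    win <- max(1L, ipk - half_max):min(length(dev), ipk + half_max)
    ev[[i]] <- c(lo, hi, peak, z[ipk], sum(sm[win] >= half))
  }
  ev <- do.call(rbind, ev)
  dur_s <- ev[, 5] / fs
  keep <- dur_s >= config$min_duration / 1000 - 1 / fs &
    dur_s <= config$max_duration / 1000 + 1 / fs &
    abs(ev[, 3]) >= config$amplitude_factor * baseline$background_uV
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)

  ord <- order(ev[, 1])
  ev <- ev[ord, , drop = FALSE]
  onset <- (ev[, 1] - 1) / fs
  offset <- ev[, 2] / fs
  keep <- rep(TRUE, nrow(ev))
  last_off <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (onset[i] < last_off + config$refractory / 1000) {
      keep[i] <- FALSE
    } else {
      last_off <- offset[i]
    }
  }
  out <- tibble::tibble(
    channel = s$channel,
    onset_s = onset[keep], offset_s = offset[keep],
    duration_ms = ev[keep, 5] / fs * 1000,
    peak_uV = ev[keep, 3], peak_score = ev[keep, 4])
  class(out) <- c("spike_events", class(out))
  out
}

#' Score detections against ground truth
#'
#' Matches detected spikes to annotated true spikes one-to-one, greedily by
#' onset proximity within `tolerance_ms`. Sensitivity is the fraction of
#' true spikes matched. Because false-positive time is not a point process,
#' specificity is computed on time bins: non-excluded session time is cut
#' into `bin_ms` bins, bins overlapping no true spike are the negatives, and
#' specificity is the fraction of negative bins free of any detection.
#'
#' @param detected A `spike_events` tibble (or any tibble with `onset_s`,
#'   `offset_s`).
#' @param truth Tibble of true spike intervals (`onset_s`, `offset_s`), e.g.
#'   `annotation_events(annotation, "spike")`.
#' @param total_duration Session duration in seconds (defines the binned
#'   timeline).
#' @param tolerance_ms Onset matching tolerance in ms. Default 50.
#' @param bin_ms Specificity bin width in ms. Default 50 (one spike width).
#' @param exclude Optional intervals removed from the binned timeline
#'   (seizures, stimulation epochs).
#' @return One-row tibble of class `detection_report`: `sensitivity`,
#'   `specificity`, `n_true`, `n_detected`, `n_matched`, `n_false_bins`,
#'   `n_negative_bins`.
#' @export
evaluate_detection <- function(detected, truth, total_duration,
                               tolerance_ms = 50, bin_ms = 50,
                               exclude = NULL) {
  if (tolerance_ms < 0) abort("`tolerance_ms` must be >= 0")
  det_on <- sort(detected$onset_s)
  tru <- tibble::as_tibble(truth)
  n_true <- nrow(tru)
  n_det <- length(det_on)

  n_matched <- 0L
  if (n_true > 0 && n_det > 0) {
    tol <- tolerance_ms / 1000
    pairs <- purrr::map_dfr(seq_len(n_det), function(i) {
      d <- abs(tru$onset_s - det_on[i])
      j <- which(d <= tol)
      if (!length(j)) return(NULL)
      tibble::tibble(det = i, tru = j, dist = d[j])
    })
    if (nrow(pairs) > 0) {
      pairs <- pairs[order(pairs$dist), ]
      used_d <- logical(n_det); used_t <- logical(n_true)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs$det[k]; j <- pairs$tru[k]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  sensitivity <- if (n_true > 0) n_matched / n_true else NA_real_

  bw <- bin_ms / 1000
  n_bins <- floor(total_duration / bw)
  mark <- function(on, off) {
    flag <- logical(n_bins)
    for (i in seq_along(on)) {
      b0 <- max(1L, floor(on[i] / bw) + 1L)
      b1 <- min(n_bins, ceiling(off[i] / bw))
      if (b0 <= b1) flag[b0:b1] <- TRUE
    }
    flag
  }
  excluded <- if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0) {
    iv <- tibble::as_tibble(exclude)
    mark(iv$onset_s %||% iv$start_s, iv$offset_s %||% iv$end_s)
  } else logical(n_bins)
  pos <- if (n_true > 0) mark(tru$onset_s, tru$offset_s) else logical(n_bins)
  hit <- if (n_det > 0) mark(detected$onset_s, detected$offset_s) else logical(n_bins)
  neg <- !pos & !excluded
  n_neg <- sum(neg)
  n_fp <- sum(neg & hit)
  specificity <- if (n_neg > 0) 1 - n_fp / n_neg else NA_real_

  out <- tibble::tibble(
    sensitivity = sensitivity, specificity = specificity,
    n_true = n_true, n_detected = n_det, n_matched = n_matched,
    n_false_bins = n_fp, n_negative_bins = n_neg)
  class(out) <- c("detection_report", class(out))
  out
}

#' Calibrate the detection threshold per subject
#'
#' Sweeps the threshold constant `C` over a grid, scoring each value's
#' sensitivity and specificity against an annotated stretch of data, and
#' returns the `C` maximizing the mean of the two subject to both being at
#' least `criterion` (85%, the per-rat calibration target); ties go to the
#' larger, more conservative `C`. When no grid value meets the criterion the
#' best-scoring `C` is returned with `criterion_met = FALSE`.
#'
#' @inheritParams detect_spikes
#' @param truth True spike intervals (tibble with `onset_s`, `offset_s`);
#'   at least 5 annotated spikes are required.
#' @param grid Numeric vector of candidate `C` values.
#'   Default `c(4, 9, 16, 25, 36, 49)` (2-7 baseline SDs).
#' @param total_duration Session duration in seconds (defaults to the
#'   recording length).
#' @param criterion Sensitivity/specificity floor. Default 0.85.
#' @param tolerance_ms,bin_ms Passed to [evaluate_detection()].
#' @return A list of class `spike_calibration`: `chosen_C`,
#'   `criterion_met`, `report` (the chosen `C`'s [evaluate_detection()]
#'   row), and `sweep` (one row per grid value).
#' @export
calibrate_threshold <- function(signal, baseline, truth,
                                grid = c(4, 9, 16, 25, 36, 49),
                                config = detector_config(),
                                channel = NULL, sampling_rate = NULL,
                                exclude = NULL, total_duration = NULL,
                                criterion = 0.85,
                                tolerance_ms = 50, bin_ms = 50) {
  if (length(grid) == 0) abort("`grid` of C values must be non-empty")
  truth <- tibble::as_tibble(truth)
  if (nrow(truth) < 5)
    abort("calibration requires at least 5 annotated true spikes")
  s <- resolve_signal(signal, channel %||% baseline$channel, sampling_rate)
  total_duration <- total_duration %||% (length(s$x) / s$fs)

  sweep <- purrr::map_dfr(sort(grid), function(C) {
    cfg <- config
    cfg$C <- C
    det <- detect_spikes(s$x, baseline, cfg, sampling_rate = s$fs,
                         exclude = exclude)
    rep <- evaluate_detection(det, truth, total_duration,
                              tolerance_ms = tolerance_ms, bin_ms = bin_ms,
                              exclude = exclude)
    dplyr::bind_cols(tibble::tibble(C = C), rep)
  })
  sweep$mean_score <- (sweep$sensitivity + sweep$specificity) / 2
  ok <- !is.na(sweep$mean_score) &
    sweep$sensitivity >= criterion & sweep$specificity >= criterion
  pool <- if (any(ok)) which(ok) else seq_len(nrow(sweep))
  best <- pool[order(-sweep$mean_score[pool], -sweep$C[pool])][1]

  structure(
    list(chosen_C = sweep$C[best],
         criterion_met = any(ok),
         criterion = criterion,
         report = sweep[best, setdiff(names(sweep), "C")],
         sweep = sweep),
    class = "spike_calibration")
}

#' @export
print.spike_calibration <- function(x, ...) {
  cat(sprintf("<spike_calibration> chosen C = %g (criterion %s)\n",
              x$chosen_C,
              if (x$criterion_met) "met" else "NOT met"))
  cat(sprintf("  sensitivity %.3f, specificity %.3f (%d true, %d detected)\n",
              x$report$sensitivity, x$report$specificity,
              x$report$n_true, x$report$n_detected))
  invisible(x)
}

#' @rdname calibrate_threshold
#' @param x A `spike_calibration` object.
#' @param ... Unused.
#' @export
tidy.spike_calibration <- function(x, ...) x$sweep

#' @rdname calibrate_threshold
#' @export
glance.spike_calibration <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(chosen_C = x$chosen_C, criterion_met = x$criterion_met),
    x$report[, c("sensitivity", "specificity", "n_true", "n_detected")])
}
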