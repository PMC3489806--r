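# Shared fixtures and independent oracles for the test suite.

# hand-built baseline model (bypasses estimation)
make_baseline <- function(mu = 0, sigma2 = 1, background = NULL,
                          channel = "CA3") {
  out <- tibble::tibble(
    channel = channel, mu = mu, sigma2 = sigma2,
    background_uV = background %||% (qnorm(0.975) * sqrt(sigma2)),
    segment_start = 0, segment_end = 60, n = 60 * 512)
  class(out) <- c("baseline_model", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small annotated session: noise + spikes (+ optional seizures)
quick_session <- function(duration = 300, spike_rate = 8,
                          schedule = NULL, amplitude_factor = 3,
                          seed = 11, sampling_rate = 512, ...) {
  cfg <- generator_config(
    sampling_rate = sampling_rate, session_duration = duration,
    spike_rate = spike_rate, spike_amplitude_factor = amplitude_factor,
    seizure_schedule = schedule, seed = seed, ...)
  list(config = cfg, session = generate_session(cfg))
}

# Brute-force spike detector: naive per-sample scan applying every rule of
# the detection contract independently of the package implementation.
brute_force_spikes <- function(x, fs, baseline, config, exclude = NULL) {
  dev <- x - baseline$mu
  z <- dev^2 / baseline$sigma2
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      i0 <- max(1, floor(exclude$onset_s[i] * fs) + 1)
      i1 <- min(length(z), ceiling(exclude$offset_s[i] * fs))
      if (i0 <= i1) z[i0:i1] <- 0
    }
  }
  # maximal supra-threshold runs, one sample at a time
  runs <- list()
  inside <- FALSE
  for (i in seq_along(z)) {
    if (z[i] > config$C && !inside) {
      start <- i; inside <- TRUE
    }
    if (inside && (z[i] <= config$C)) {
      runs[[length(runs) + 1]] <- c(start, i - 1)
      inside <- FALSE
    }
  }
  if (inside) runs[[length(runs) + 1]] <- c(start, length(z))
  if (!length(runs)) return(data.frame())
  # merge across short gaps
  gap_max <- config$merge_gap / 1000 * fs
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if (r[1] - prev[2] - 1 < gap_max) {
      merged[[length(merged)]] <- c(prev[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  # expand each run to its half-amplitude region and apply every filter
  cap <- round(0.25 * fs)
  ev <- list()
  for (r in merged) {
    seg <- r[1]:r[2]
    # apex: raw extremum within one sample of the best 3-sample local mean
    best <- -Inf; ism <- seg[1]
    for (i in seg) {
      a_prev <- abs(dev[max(1, i - 1)])
      a_next <- abs(dev[min(length(dev), i + 1)])
      m3 <- (abs(dev[i]) + a_prev + a_next) / 3
      if (m3 > best) { best <- m3; ism <- i }
    }
    cand <- max(1, ism - 1):min(length(dev), ism + 1)
    ipk <- cand[which.max(abs(dev[cand]))]
    half <- abs(dev[ipk]) / 2
    smooth_at <- function(i) {
      mean(abs(dev[c(max(1, i - 1), i, min(length(dev), i + 1))]))
    }
    lo <- ipk; j <- ipk; gap <- 0
    while (j > 1 && ipk - j < cap) {
      j <- j - 1
      if (smooth_at(j) >= half) { lo <- j; gap <- 0 }
      else { gap <- gap + 1; if (gap >= 2) break }
    }
    hi <- ipk; j <- ipk; gap <- 0
    while (j < length(dev) && j - ipk < cap) {
      j <- j + 1
      if (smooth_at(j) >= half) { hi <- j; gap <- 0 }
      else { gap <- gap + 1; if (gap >= 2) break }
    }
    # duration: count of smoothed samples above half within +/- cap of apex
    n_supra <- 0
    for (j in max(1, ipk - cap):min(length(dev), ipk + cap)) {
      if (smooth_at(j) >= half) n_supra <- n_supra + 1
    }
    dur <- n_supra / fs
    ok_dur <- dur >= config$min_duration / 1000 - 1 / fs &&
      dur <= config$max_duration / 1000 + 1 / fs
    ok_amp <- abs(dev[ipk]) >= config$amplitude_factor * baseline$background_uV
    if (ok_dur && ok_amp)
      ev[[length(ev) + 1]] <- data.frame(lo = lo, hi = hi,
                                         peak = dev[ipk], score = z[ipk])
  }
  if (!length(ev)) return(data.frame())
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$lo), ]
  keep <- logical(nrow(ev))
  last_off <- -Inf
  for (i in seq_len(nrow(ev))) {
    onset <- (ev$lo[i] - 1) / fs
    if (onset >= last_off + config$refractory / 1000) {
      keep[i] <- TRUE
      last_off <- ev$hi[i] / fs
    }
  }
  ev <- ev[keep, ]
  data.frame(onset_s = (ev$lo - 1) / fs, offset_s = ev$hi / fs,
             peak_uV = ev$peak, peak_score = ev$score)
}

# Independent split-plot sums-of-squares decomposition (balanced designs)
rm_anova_oracle <- function(d) {
  # d: data.frame with columns value, subject, day, group
  D <- length(unique(d$day))
  subj <- unique(d$subject)
  N <- length(subj)
  grp_of <- tapply(as.character(d$group), d$subject, function(v) v[1])
  G <- length(unique(grp_of))
  m <- mean(d$value)
  m_s <- tapply(d$value, d$subject, mean)
  m_g <- tapply(m_s, grp_of[names(m_s)], mean)
  n_g <- table(grp_of)
  m_d <- tapply(d$value, d$day, mean)
  cell <- tapply(d$value, list(d$group, d$day), mean)

  ss_between_subj <- D * sum((m_s - m)^2)
  ss_group <- D * sum(n_g[names(m_g)] * (m_g - m)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_day <- N * sum((m_d - m)^2)
  ss_int <- 0
  for (g in rownames(cell)) for (dd in colnames(cell)) {
    ss_int <- ss_int + n_g[[g]] * (cell[g, dd] - m_g[[g]] - m_d[[dd]] + m)^2
  }
  ss_within_subj <- sum((d$value - m_s[as.character(d$subject)])^2)
  ss_err_within <- ss_within_subj - ss_day - ss_int
  df_g <- G - 1; df_sg <- N - G
  df_d <- D - 1; df_int <- (G - 1) * (D - 1)
  df_err <- (D - 1) * (N - G)
  list(
    F_group = (ss_group / df_g) / (ss_subj_within / df_sg),
    F_day = (ss_day / df_d) / (ss_err_within / df_err),
    F_int = (ss_int / df_int) / (ss_err_within / df_err),
    df = list(group = c(df_g, df_sg), day = c(df_d, df_err),
              int = c(df_int, df_err)),
    ss_total = sum((d$value - m)^2),
    ss_between_subj = ss_between_subj,
    ss_within_subj = ss_within_subj)
}

# interval matching by temporal overlap (for segmentation recall/precision)
match_intervals <- function(detected, truth) {
  if (nrow(detected) == 0 || nrow(truth) == 0) {
    return(list(tp = 0, n_det = nrow(detected), n_true = nrow(truth)))
  }
  hit_true <- logical(nrow(truth))
  hit_det <- logical(nrow(detected))
  for (i in seq_len(nrow(detected))) {
    for (j in seq_len(nrow(truth))) {
      if (detected$onset_s[i] < truth$offset_s[j] &&
          detected$offset_s[i] > truth$onset_s[j]) {
        hit_true[j] <- TRUE
        hit_det[i] <- TRUE
      }
    }
  }
  list(tp = sum(hit_true), n_det = nrow(detected), n_true = nrow(truth),
       det_matched = sum(hit_det))
}
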