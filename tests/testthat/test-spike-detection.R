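test_that("baseline estimation recovers sample moments and rejects degenerates", {
  expect_error(estimate_baseline(rep(5, 2048), c(0, 4), sampling_rate = 512),
               "zero variance")
  expect_error(estimate_baseline(rnorm(512), c(0, 0.5), sampling_rate = 512),
               "1 s")

  set.seed(31)
  x <- rnorm(60 * 512)
  bl <- estimate_baseline(x, c(0, 60), sampling_rate = 512)
  expect_lt(abs(bl$mu), 0.1)
  expect_lt(abs(bl$sigma2 - 1), 0.1)
  # envelope close to the Gaussian 95% quantile of |x|
  expect_lt(abs(bl$background_uV - qnorm(0.975)) / qnorm(0.975), 0.05)

  # affine transform: moment identities hold exactly
  a <- -2.5; b <- 7
  bl2 <- estimate_baseline(a * x + b, c(0, 60), sampling_rate = 512)
  expect_equal(bl2$mu, a * bl$mu + b, tolerance = 1e-12)
  expect_equal(bl2$sigma2, a^2 * bl$sigma2, tolerance = 1e-12)
})

test_that("sample scores are the squared standardized deviation, monotone in rarity", {
  bl <- make_baseline(mu = 3, sigma2 = 4)
  s <- sqrt(bl$sigma2)
  x <- c(3, 3 + s, 3 + 3 * s, 3 - 2 * s)
  expect_equal(score_samples(x, bl, sampling_rate = 512), c(0, 1, 9, 4))

  set.seed(1)
  xs <- rnorm(200, 3, s)
  sc <- score_samples(xs, bl, sampling_rate = 512)
  dens <- dnorm(xs, 3, s)
  expect_identical(order(sc), rev(order(dens)))
})

test_that("detector finds injected spikes and applies the duration band", {
  set.seed(12)
  fs <- 512
  bl <- make_baseline(mu = 0, sigma2 = 25)    # sigma 5, background ~9.8
  x <- rnorm(60 * fs, 0, 5)
  # C = 25 on pure noise: P(|z| > 5 sd) ~ 5.7e-7/sample -> expect none
  det0 <- detect_spikes(x, bl, detector_config(C = 25), sampling_rate = fs)
  expect_equal(nrow(det0), 0)

  # 40 ms spikes at 3x background: one event each, onset/offset accurate
  # to a few ms on average (single-event jitter is noise-limited)
  amp <- 3 * bl$background_uV
  w <- synth_spike_waveform(40, amp, 1, fs)
  x1 <- x
  apices <- seq(5, 55, by = 10)
  for (at in apices) {
    i0 <- at * fs - (attr(w, "peak_index") - 1)
    x1[i0 + seq_along(w) - 1] <- x1[i0 + seq_along(w) - 1] + w
  }
  det1 <- detect_spikes(x1, bl, detector_config(C = 9), sampling_rate = fs)
  expect_equal(nrow(det1), length(apices))
  apex_s <- (apices * fs - 1) / fs
  on_err <- det1$onset_s - (apex_s - 0.020)
  off_err <- det1$offset_s - (apex_s + 0.020)
  expect_lt(mean(abs(on_err)), 0.005)
  expect_lt(mean(abs(off_err)), 0.005)
  expect_true(all(abs(c(on_err, off_err)) < 0.015))

  # 10 ms and 100 ms transients at 3x background: rejected by the band
  x2 <- x
  for (spec in list(c(10, 15), c(100, 45))) {
    w <- synth_spike_waveform(spec[1], amp, 1, fs)
    j0 <- spec[2] * fs - (attr(w, "peak_index") - 1)
    x2[j0 + seq_along(w) - 1] <- x2[j0 + seq_along(w) - 1] + w
  }
  det2 <- detect_spikes(x2, bl, detector_config(C = 9), sampling_rate = fs)
  expect_equal(nrow(det2), 0)

  expect_error(detector_config(C = -1), "C")
  expect_error(detect_spikes(x[1:10], bl, sampling_rate = fs), "max_duration")
})

test_that("duration filter admits exactly the 20-70 ms band on clean transients", {
  fs <- 512
  bl <- make_baseline(mu = 0, sigma2 = 25)
  for (d in c(5, 10, 15, 20, 30, 45, 60, 70, 85, 100, 150)) {
    x <- rep(0, 30 * fs)
    x <- x + rnorm(length(x), 0, 1e-3) # break exact zero variance ties
    w <- synth_spike_waveform(d, 6 * sqrt(bl$sigma2), 1, fs)
    i0 <- 15 * fs - (attr(w, "peak_index") - 1)
    x[i0 + seq_along(w) - 1] <- x[i0 + seq_along(w) - 1] + w
    det <- detect_spikes(x, bl, detector_config(C = 9), sampling_rate = fs)
    expect_equal(nrow(det), as.integer(d >= 20 && d <= 70),
                 info = sprintf("duration %d ms", d))
  }
})

test_that("detect_spikes equals the brute-force rule oracle on short signals", {
  fs <- 512
  cfg <- detector_config(C = 9)
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(3000:10000, 1)
    x <- rnorm(n, 0, 5)
    bl <- make_baseline(mu = 0, sigma2 = 25)
    # inject a handful of transients of assorted widths/amplitudes
    for (k in 1:6) {
      d <- sample(c(10, 25, 40, 65, 90), 1)
      amp <- runif(1, 2, 5) * bl$background_uV
      w <- synth_spike_waveform(d, amp, sample(c(-1, 1), 1), fs)
      at <- sample(seq(fs, n - fs), 1)
      idx <- at + seq_along(w) - 1
      x[idx] <- x[idx] + w
    }
    excl <- tibble::tibble(onset_s = 1.0, offset_s = 1.5)
    det <- detect_spikes(x, bl, cfg, sampling_rate = fs, exclude = excl)
    bf <- brute_force_spikes(x, fs, bl, cfg, exclude = excl)
    expect_equal(nrow(det), nrow(bf))
    if (nrow(det) > 0) {
      expect_equal(det$onset_s, bf$onset_s, tolerance = 1e-12)
      expect_equal(det$offset_s, bf$offset_s, tolerance = 1e-12)
      expect_equal(det$peak_uV, bf$peak_uV, tolerance = 1e-12)
    }
  }
})

test_that("detection is invariant to affine rescaling with re-estimated baseline", {
  qs <- quick_session(duration = 180, spike_rate = 10, seed = 14)
  rec <- qs$session$recording
  bl <- estimate_baseline(rec, c(0, 60), channel = "CA3")
  det <- detect_spikes(rec, bl, detector_config(C = 9), channel = "CA3")

  y <- 0.25 * rec$CA3_uV - 40
  bly <- estimate_baseline(y, c(0, 60), sampling_rate = 512)
  dety <- detect_spikes(y, bly, detector_config(C = 9), sampling_rate = 512)
  expect_equal(det$onset_s, dety$onset_s)
  expect_equal(det$offset_s, dety$offset_s)
})

test_that("detection report counts a hand-built confusion matrix correctly", {
  truth <- tibble::tibble(onset_s = seq(5, 50, by = 5) - 0.02,
                          offset_s = seq(5, 50, by = 5) + 0.02)
  det_perfect <- tibble::tibble(onset_s = truth$onset_s,
                                offset_s = truth$offset_s)
  r <- evaluate_detection(det_perfect, truth, total_duration = 60)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r0 <- evaluate_detection(det_perfect[0, ], truth, total_duration = 60)
  expect_equal(r0$sensitivity, 0)

  det8 <- det_perfect[1:8, ]
  r8 <- evaluate_detection(det8, truth, total_duration = 60)
  expect_equal(r8$sensitivity, 0.8)
  expect_equal(r8$specificity, 1)
  expect_equal(r8$n_matched, 8L)

  # one spurious detection away from truth lowers specificity
  det_fp <- dplyr::bind_rows(det8, tibble::tibble(onset_s = 57.02, offset_s = 57.06))
  rfp <- evaluate_detection(det_fp, truth, total_duration = 60)
  expect_lt(rfp$specificity, 1)
  expect_equal(rfp$n_false_bins, 2L) # a 40 ms event spans two 50 ms bins

  expect_error(evaluate_detection(det8, truth, 60, tolerance_ms = -1), ">= 0")
})

test_that("threshold calibration meets the 85% criterion on separable data", {
  qs <- quick_session(duration = 600, spike_rate = 8, seed = 19)
  rec <- qs$session$recording
  bl <- estimate_baseline(rec, c(0, 60), channel = "CA3")
  truth <- annotation_events(qs$session$annotation, "spike")
  cal <- calibrate_threshold(rec, bl, truth, channel = "CA3")
  expect_true(cal$criterion_met)
  expect_gte(cal$report$sensitivity, 0.85)
  expect_gte(cal$report$specificity, 0.85)

  # monotonicity of the sweep in C, at event/bin granularity: the sample
  # thresholding stage is strictly monotone; the event-level merge and
  # duration rules can shift at most a single event across grid points
  sw <- tidy(cal)
  expect_true(all(diff(sw$sensitivity) <= 1 / sw$n_true[1] + 1e-12))
  expect_true(all(diff(sw$specificity) >= -1.5 / sw$n_negative_bins[1]))
  # and the trend over the whole grid is monotone
  expect_lte(sw$sensitivity[nrow(sw)], sw$sensitivity[1] + 1e-12)
  expect_gte(sw$specificity[nrow(sw)], sw$specificity[1] - 1e-12)

  # shuffled (random) labels: criterion unreachable
  set.seed(99)
  fake <- truth
  fake$onset_s <- sort(runif(nrow(fake), 61, 590))
  fake$offset_s <- fake$onset_s + 0.04
  cal_bad <- calibrate_threshold(rec, bl, fake, channel = "CA3")
  expect_false(cal_bad$criterion_met)

  expect_error(calibrate_threshold(rec, bl, truth, grid = numeric(0),
                                   channel = "CA3"), "non-empty")
  expect_error(calibrate_threshold(rec, bl, truth[1:3, ], channel = "CA3"),
               "at least 5")
})

test_that("calibrated detection recovers the generator spike rate within 15%", {
  qs <- quick_session(duration = 600, spike_rate = 8, seed = 23)
  rec <- qs$session$recording
  bl <- estimate_baseline(rec, c(0, 60), channel = "CA3")
  truth <- annotation_events(qs$session$annotation, "spike")
  cal <- calibrate_threshold(rec, bl, truth, channel = "CA3")
  det <- detect_spikes(rec, bl, detector_config(C = cal$chosen_C),
                       channel = "CA3")
  true_rate <- nrow(truth) / (600 / 60)
  det_rate <- nrow(det) / (600 / 60)
  expect_lt(abs(det_rate - true_rate) / true_rate, 0.15)
})
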