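test_that("baseline noise matches its nominal moments and is reproducible", {
  cfg <- generator_config(baseline_mu = 0, baseline_sigma = 10, seed = 42)
  x <- generate_baseline_noise(cfg, 60)
  n <- length(x)
  expect_equal(n, 60 * 512)
  expect_lt(abs(mean(x)), 3 * 10 / sqrt(n))
  expect_lt(abs(sd(x) - 10) / 10, 0.05)

  y <- generate_baseline_noise(cfg, 60)
  expect_identical(x, y)

  cfg0 <- generator_config(baseline_mu = 5, baseline_sigma = 0)
  expect_identical(generate_baseline_noise(cfg0, 1), rep(5, 512))
  expect_error(generate_baseline_noise(cfg, -1), "positive")

  cfgp <- generator_config(baseline_mu = 2, baseline_sigma = 10,
                           noise_kind = "pink", seed = 3)
  p <- generate_baseline_noise(cfgp, 60)
  expect_lt(abs(sd(p) - 10) / 10, 0.05)
  expect_lt(abs(mean(p) - 2), 1)
})

test_that("spike waveform honours peak, polarity and half-amplitude width", {
  w <- synth_spike_waveform(40, 100, 1, 512)
  expect_equal(max(abs(w)), 100)
  expect_equal(w[attr(w, "peak_index")], 100)

  wm <- synth_spike_waveform(40, 100, -1, 512)
  expect_equal(as.numeric(wm), -as.numeric(w))

  for (d in c(20, 40, 70)) {
    w <- synth_spike_waveform(d, 50, 1, 512)
    width_s <- sum(abs(w) >= 25) / 512
    expect_lt(abs(width_s - d / 1000), 1 / 512 + 1e-12)
  }
  expect_error(synth_spike_waveform(40, -5), "> 0")
  expect_error(synth_spike_waveform(0, 5), "duration")
})

test_that("empty schedule and zero spike rate give pure noise", {
  qs <- quick_session(duration = 120, spike_rate = 0, seed = 5)
  ann <- qs$session$annotation
  expect_identical(unique(ann$event_type), "injection")
  x <- qs$session$recording$CA3_uV
  expect_lt(max(abs(x - mean(x))) / sd(x), 6) # Gaussian tail, no transients
})

test_that("annotated spike count falls in the Poisson interval of the rate", {
  qs <- quick_session(duration = 1800, spike_rate = 10, seed = 21)
  n_spk <- nrow(annotation_events(qs$session$annotation, "spike"))
  lambda <- 10 * 30
  expect_gt(n_spk, qpois(0.005, lambda) - 0.05 * lambda) # 99% band, small thinning allowance
  expect_lt(n_spk, qpois(0.995, lambda))
})

test_that("generalization delay is echoed exactly in the annotation", {
  sched <- data.frame(onset_s = 150, duration_s = 40, class = "generalized",
                      stage = "IV", generalization_delay_s = 2)
  qs <- quick_session(duration = 300, spike_rate = 0, schedule = sched, seed = 9)
  sz <- annotation_events(qs$session$annotation, "seizure")
  expect_setequal(sz$channel, c("CA3", "MCX"))
  expect_equal(sz$onset_s[sz$channel == "MCX"] - sz$onset_s[sz$channel == "CA3"],
               2, tolerance = 1 / 512)
})

test_that("session generation is deterministic under a fixed seed", {
  sched <- data.frame(onset_s = 100, duration_s = 30, class = "focal", stage = "II")
  a <- quick_session(duration = 200, spike_rate = 5, schedule = sched, seed = 77)
  b <- quick_session(duration = 200, spike_rate = 5, schedule = sched, seed = 77)
  expect_identical(a$session$recording$CA3_uV, b$session$recording$CA3_uV)
  expect_identical(as.data.frame(a$session$annotation),
                   as.data.frame(b$session$annotation))
})

test_that("ground-truth invariants hold across generated sessions", {
  sched <- data.frame(onset_s = c(200, 400), duration_s = c(40, 50),
                      class = c("focal", "generalized"),
                      stage = c("II", "V"))
  for (seed in c(1, 2, 3)) {
    qs <- quick_session(duration = 600, spike_rate = 6, schedule = sched,
                        seed = seed)
    ann <- qs$session$annotation
    spk <- annotation_events(ann, "spike")
    dur_ms <- (spk$offset_s - spk$onset_s) * 1000
    expect_true(all(dur_ms >= 20 - 1e-9 & dur_ms <= 70 + 1e-9))
    # every true spike's clean amplitude reaches the configured envelope
    # multiple; the rendered (noisy) peak stays well above background
    bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
    expect_true(all(as.numeric(spk$label) >=
                      3 * qnorm(0.975) * 50 - 1e-3))
    dev <- abs(qs$session$recording$CA3_uV - bl$mu)
    apex <- round((spk$onset_s + spk$offset_s) / 2 * 512) + 1
    peaks <- vapply(apex, function(i) max(dev[(i - 5):(i + 5)]), numeric(1))
    expect_true(all(peaks >= 2.5 * bl$background_uV))
    sz <- annotation_events(ann, "seizure")
    expect_lte(sum(sz$offset_s - sz$onset_s), qs$config$session_duration * 2)
    expect_setequal(sz$channel[sz$label == "generalized"], c("CA3", "MCX"))
    expect_identical(unique(sz$channel[sz$label == "focal"]), "CA3")
  }
})

test_that("scheduled status epilepticus yields one ictal interval over 30 min", {
  cfg <- generator_config(sampling_rate = 64, session_duration = 2400,
                          spike_rate = 0, se_flag = TRUE, seed = 4)
  ses <- generate_session(cfg)
  sz <- annotation_events(ses$annotation, "seizure")
  ca3 <- sz[sz$channel == "CA3", ]
  expect_equal(nrow(ca3), 1)
  expect_gt(ca3$offset_s - ca3$onset_s, 1800)
})

test_that("overlapping scheduled seizures are rejected", {
  sched <- data.frame(onset_s = c(100, 120), duration_s = c(40, 30),
                      class = "focal", stage = "I")
  expect_error(generator_config(session_duration = 300, seizure_schedule = sched),
               "overlap")
  bad <- data.frame(onset_s = 100, duration_s = 30, class = "focal", stage = "V")
  expect_error(generator_config(session_duration = 300, seizure_schedule = bad),
               "stage/class")
})

test_that("cohorts carry labels, positive Day-1 counts and a null option", {
  co <- generate_cohort(c(hfs = 3, sham = 3), days = 3, seed = 8,
                        build_configs = TRUE)
  expect_equal(nrow(co), 18)
  expect_setequal(unique(co$day), 1:3)
  expect_setequal(unique(co$group), c("hfs", "sham"))
  expect_true(all(co$n_focal_true[co$day == 1] >= 1))
  expect_true(all(co$n_focal_true >= 0 & co$n_generalized_true >= 0))
  # each config's schedule matches its truth counts and validates
  for (i in seq_len(nrow(co))) {
    sch <- co$config[[i]]$seizure_schedule
    expect_equal(sum(sch$class == "focal"), co$n_focal_true[i])
    expect_equal(sum(sch$class == "generalized"), co$n_generalized_true[i])
  }
  eff <- cohort_effect_null()
  expect_identical(eff$focal_mean["hfs", ], eff$focal_mean["sham", ])
  expect_error(generate_cohort(c(hfs = 1, sham = 3)), "at least 2")
})
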