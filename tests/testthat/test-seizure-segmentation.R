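test_that("segmentation finds nothing in pure baseline noise", {
  qs <- quick_session(duration = 300, spike_rate = 0, seed = 41)
  bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
  seg <- segment_seizures(qs$session$recording, bl, channel = "CA3")
  expect_equal(nrow(seg), 0)
  expect_error(segment_seizures(rnorm(256), bl, sampling_rate = 512),
               "window longer")
})

test_that("a scheduled seizure is recovered with tight onset and offset", {
  sched <- data.frame(onset_s = 600, duration_s = 60, class = "generalized",
                      stage = "V", generalization_delay_s = 2)
  qs <- quick_session(duration = 900, spike_rate = 0, schedule = sched, seed = 43)
  bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
  seg <- segment_seizures(qs$session$recording, bl, channel = "CA3")
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$onset_s - 600), 2)
  expect_lt(abs(seg$offset_s - 660), 5)
})

test_that("seizures closer than the merge gap come back as one interval", {
  sched <- data.frame(onset_s = c(150, 188), duration_s = c(30, 30),
                      class = "focal", stage = "II")
  qs <- quick_session(duration = 300, spike_rate = 0, schedule = sched, seed = 47)
  bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
  seg <- segment_seizures(qs$session$recording, bl, channel = "CA3")
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$onset_s - 150), 3)
})

test_that("classification follows the two-channel plus stage rules", {
  ca3 <- tibble::tibble(onset_s = c(100, 300, 500), offset_s = c(140, 360, 540))
  mcx <- tibble::tibble(onset_s = 305, offset_s = 355)
  stages <- tibble::tibble(time_s = c(100, 305, 505), stage = c("II", "V", "V"))
  ev <- classify_seizures(ca3, mcx, stages)
  expect_equal(ev$class, c("focal", "generalized", "unclassified"))
  expect_equal(ev$channels, c("CA3", "CA3+MCX", "CA3"))
  expect_equal(ev$stage, c("II", "V", "V"))

  # CA3+MCX overlap but mild stage: conflict surfaced, not coerced
  ev2 <- classify_seizures(tibble::tibble(onset_s = 300, offset_s = 360),
                           mcx, tibble::tibble(time_s = 310, stage = "I"))
  expect_equal(ev2$class, "unclassified")

  expect_error(
    classify_seizures(ca3, mcx, tibble::tibble(time_s = 100, stage = "II")),
    "no Racine stage")
})

test_that("status epilepticus flags single events and chains over 30 min", {
  ev1 <- tibble::tibble(onset_s = 100, offset_s = 2000, class = "generalized")
  expect_true(detect_status_epilepticus(ev1)$is_se)

  ev2 <- tibble::tibble(onset_s = 100, offset_s = 1800, class = "generalized")
  expect_false(detect_status_epilepticus(ev2)$is_se)

  # three 700 s events separated by 5 s: chain spans 2110 s
  ev3 <- tibble::tibble(onset_s = c(0, 705, 1410),
                        offset_s = c(700, 1405, 2110), class = "focal")
  expect_true(all(detect_status_epilepticus(ev3)$is_se))

  # same events separated by 20 s: three independent sub-SE events
  ev4 <- tibble::tibble(onset_s = c(0, 720, 1440),
                        offset_s = c(700, 1420, 2140), class = "focal")
  expect_false(any(detect_status_epilepticus(ev4)$is_se))
})

test_that("segmentation recall and precision reach 0.9 on high-SNR sessions", {
  tp <- 0; n_true <- 0; n_det <- 0; det_matched <- 0
  for (seed in c(61, 62)) {
    sched <- data.frame(onset_s = c(200, 400, 650), duration_s = c(40, 60, 35),
                        class = c("focal", "generalized", "focal"),
                        stage = c("II", "IV", "I"))
    qs <- quick_session(duration = 900, spike_rate = 4, schedule = sched,
                        seed = seed)
    bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
    seg <- segment_seizures(qs$session$recording, bl, channel = "CA3")
    truth <- annotation_events(qs$session$annotation, "seizure")
    truth <- truth[truth$channel == "CA3", ]
    m <- match_intervals(seg, truth)
    tp <- tp + m$tp; n_true <- n_true + m$n_true
    n_det <- n_det + m$n_det; det_matched <- det_matched + m$det_matched
    # no overlapping intervals after merging
    if (nrow(seg) > 1)
      expect_true(all(seg$onset_s[-1] >= seg$offset_s[-nrow(seg)]))
  }
  expect_gte(tp / n_true, 0.9)
  expect_gte(det_matched / n_det, 0.9)
})

test_that("responsive trigger is causal with construction-bounded latency", {
  qs0 <- quick_session(duration = 300, spike_rate = 0, seed = 71)
  bl0 <- estimate_baseline(qs0$session$recording, c(0, 60), channel = "CA3")
  expect_equal(nrow(simulate_responsive_trigger(qs0$session$recording, bl0,
                                                channel = "CA3")), 0)

  lat <- c()
  for (seed in c(73, 74)) {
    sched <- data.frame(onset_s = c(200, 500), duration_s = c(50, 60),
                        class = "focal", stage = "II")
    qs <- quick_session(duration = 800, spike_rate = 0, schedule = sched,
                        seed = seed)
    bl <- estimate_baseline(qs$session$recording, c(0, 60), channel = "CA3")
    truth <- annotation_events(qs$session$annotation, "seizure")
    trg <- simulate_responsive_trigger(qs$session$recording, bl,
                                       channel = "CA3", truth = truth)
    expect_equal(nrow(trg), 2)
    p <- segmentation_params()
    # causal: a trigger can never precede the true onset minus one window
    expect_true(all(trg$trigger_s >= trg$true_onset_s - p$window_s))
    # bounded by construction: ramp tail + sustain + window
    cfg <- qs$config
    bound <- cfg$seizure_ramp_s / 2 + p$sustain_s + p$window_s + 1
    expect_true(all(trg$latency_s > 0 & trg$latency_s <= bound))
    # stimulation persists into the seizure and stops after it ends
    expect_true(all(trg$stop_s > trg$trigger_s))
    lat <- c(lat, trg$latency_s)
  }
  # comparable order of magnitude to the few-second delays reported for
  # visually triggered responsive stimulation
  expect_lt(mean(lat), 10)
})
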