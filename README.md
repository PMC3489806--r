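# seizr

Detection and quantification of epileptiform activity in two-channel rodent
EEG, built for repeated low-dose intrahippocampal kainate experiments in
which a stimulated group is compared with sham controls across injection
days. The package is aimed at electrophysiologists who need a tested,
scriptable replacement for manual EEG review: every stage of the analysis —
spike detection, seizure segmentation, classification, session metrics,
group statistics — is an R function operating on tibbles, and a synthetic
session generator with complete ground truth makes each stage verifiable.

## The model at the core

Baseline (pre-injection) EEG amplitude is modelled as Gaussian with mean μ
and variance σ². Each sample *x* of the post-injection recording is scored
by its squared standardized deviation

    z²(x) = (x − μ)² / σ²,

a strictly decreasing transform of the baseline density f(x), and flagged
when z² exceeds an empirical constant *C*. Flagged runs become interictal
spike events when their full width at half amplitude lies in the 20–70 ms
band and their peak reaches twice the background amplitude envelope (the
95th percentile of |x − μ| on the baseline segment). *C* is calibrated per
subject by sweeping a grid and requiring sensitivity and specificity ≥ 85%
against annotated data.

Electrographic seizures are segmented by a windowed rule (spike-train
activity plus RMS ≥ 2× baseline, with a 1.5×/5 s hysteresis offset),
classified focal (CA3 only, Racine stage I–II) or generalized (synchronized
on both channels, stage III–V), and flagged as status epilepticus when a
merged ictal chain exceeds 30 min. Session metrics (counts, latencies,
durations, log₁₀ inter-seizure intervals, interictal spike rate) feed
pooled/paired *t* tests and a split-plot repeated-measures ANOVA
(group × day), including a summary-statistics form of the pooled *t* for
re-testing published mean ± SEM contrasts.

## A worked example

```r
library(seizr)

cfg <- generator_config(
  session_duration = 600, spike_rate = 6, spike_amplitude_factor = 3,
  seizure_schedule = data.frame(
    onset_s = c(250, 450), duration_s = c(40, 60),
    class = c("focal", "generalized"), stage = c("II", "IV")),
  seed = 7)
ses <- generate_session(cfg)

baseline <- estimate_baseline(ses$recording, c(0, 60), channel = "CA3")
truth    <- annotation_events(ses$annotation, "spike")
cal <- calibrate_threshold(ses$recording, baseline, truth, channel = "CA3",
                           exclude = exclusion_intervals(ses$annotation))
cal
#> <spike_calibration> chosen C = 36 (criterion met)
#>   sensitivity 0.958, specificity 1.000 (48 true, 46 detected)
```

The chosen threshold (6 baseline SDs) recovers 46 of 48 annotated spikes
with no false 50-ms bins — comfortably above the 85% calibration criterion.
Segmentation and classification recover the two scheduled seizures with
their classes and stages:

```r
ca3 <- segment_seizures(ses$recording, baseline, channel = "CA3")
mcx <- segment_seizures(ses$recording,
         estimate_baseline(ses$recording, c(0, 60), channel = "MCX"),
         channel = "MCX")
st  <- annotation_events(ses$annotation, "stage")
seizures <- classify_seizures(ca3, mcx,
              tibble::tibble(time_s = st$onset_s, stage = st$label)) |>
  detect_status_epilepticus()
seizures
#>   onset_s offset_s duration_s class       stage channels mcx_onset_s is_se
#> 1     250     290.       39.8 focal       II    CA3               NA FALSE
#> 2     450     510        60   generalized IV    CA3+MCX          452 FALSE
```

The detected focal onset lands on the annotated 250 s, the generalized
seizure is recognized on both channels with its 2 s generalization delay,
and neither lasts 30 min, so no SE flag. A reconstruction of a published
group contrast from its summary statistics alone:

```r
pooled_t_from_summary(8.9, 1.7, 7, 25.1, 5.1, 8)
#> 	Pooled two-sample t test from summary statistics
#> t = -2.8411, df = 13, p-value = 0.01391
```

i.e. Day-1 focal seizure counts of 8.9 ± 1.7 (n = 7, stimulated) versus
25.1 ± 5.1 (n = 8, sham) differ at t(13) = 2.84, p < 0.05.

`run_pipeline()` chains every stage on a YAML/list config (simulate or read
CSV signals, estimate, calibrate, segment, classify, detect, summarize) and
writes each stage's CSV/JSON output plus a reproducibility log. See the
vignette (`vignettes/seizure-spike-pipeline.Rmd`) for the model details,
conventions, and the generator's scope.

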