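---
title: "Quantifying seizures and interictal spikes in rodent EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seizures and interictal spikes in rodent EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(seizr)
library(dplyr)
```

## The analysis problem

Repeated low-dose intrahippocampal kainate injections in rats produce, within
each 90-minute monitoring session, a mixture of epileptiform events on a
two-channel EEG montage (a depth electrode in CA3 at the injection site and a
contralateral motor-cortex screw electrode, sampled at 512 Hz):

* **interictal spikes (IS)** — pointed transients of 20–70 ms, at least twice
  the background amplitude, counted per minute;
* **electrographic seizures** — spike trains whose amplitude and frequency
  ramp up at onset, classified *focal* (CA3 only, behavioural Racine stage
  I–II) or *generalized* (synchronized on both channels, stage III–V);
* **status epilepticus (SE)** — continuous seizure activity for more than
  30 minutes.

The scientific questions are comparative: does a treatment (here, responsive
high-frequency stimulation of the subiculum, HFS) change seizure counts,
latencies, durations, inter-seizure intervals, or the IS rate, across groups
and injection days? seizr implements the full chain — detection, segmentation,
classification, per-session metrics, and the group×day statistics — together
with a synthetic-session generator carrying complete ground truth, so every
stage is testable against known inputs.

## The spike detection model

The background EEG amplitude is modelled as Gaussian. From a pre-injection
baseline segment we estimate the mean $\mu$ and variance $\sigma^2$; each
later sample $x$ is scored by its squared standardized deviation

$$ z^2(x) = \frac{(x-\mu)^2}{\sigma^2}, $$

which is a strictly decreasing transform of the Gaussian density $f(x)$:
thresholding $z^2$ above a constant $C$ is exactly equivalent to flagging
samples whose amplitude is improbable under the baseline model. $C$ is kept
dimensionless (units of $\sigma^2$); the default grid
$C \in \{4, 9, 16, 25, 36, 49\}$ spans thresholds of 2–7 baseline SDs.

Supra-threshold samples form candidate runs; runs closer than 10 ms are
merged (two phases of one biphasic wave must not count twice). Each merged
run becomes one candidate event, measured as follows:

* **apex** — the raw extremum nearest the maximum of a 3-sample local mean of
  $|x-\mu|$, so that a lone noise excursion on a flank cannot set the
  amplitude reference;
* **onset/offset** — the first outward crossings of the smoothed trace below
  half the apex deviation, where a single sub-half dip does not terminate the
  scan (two consecutive sub-half samples do);
* **duration** — the total time the smoothed trace spends above half
  amplitude within ±250 ms of the apex. This count statistic is an unbiased
  estimate of the full width at half amplitude under noise; either crossing
  statistic alone is biased (the first crossing truncates shallow, long
  transients into the acceptance band; the outermost crossing inflates true
  ~70 ms spikes out of it).

An event is kept when its duration lies in the 20–70 ms band — with one
sample period (≈1.95 ms at 512 Hz) of grace at each edge, absorbing the
discretization of a continuous width — and its apex deviation reaches twice
the *background amplitude envelope*, defined as the 95th percentile of
$|x-\mu|$ over the baseline segment (for a Gaussian baseline,
$\approx 1.96\sigma$). A 50 ms refractory period suppresses events starting
immediately after a kept event. Samples inside detected seizures and
stimulation epochs are excluded beforehand: interictal spikes are interictal
by definition.

### Per-subject calibration

Electrode impedance and placement vary between animals, so $C$ is calibrated
per subject against an annotated stretch of data: the grid is swept,
sensitivity and specificity are computed for each $C$, and the chosen $C$
maximizes their mean subject to both being at least 85%; ties go to the
larger (more conservative) $C$. If no grid value qualifies, the best value is
returned flagged as failing the criterion rather than silently accepted.

Sensitivity uses greedy one-to-one onset matching within 50 ms. Specificity
needs a notion of true negatives for a point process; we bin non-ictal,
non-stimulation time into 50 ms bins (one spike width) and report the
fraction of spike-free bins that carry no detection. Whether specificity
should be counted per sample, per bin, or per event is a convention; the bin
definition is stated in the `evaluate_detection()` documentation and used
consistently.

One property worth stating precisely: as $C$ grows, the set of
supra-threshold *samples* shrinks monotonically, but the event-level merge
and duration rules can occasionally move a single event across adjacent grid
points (a run that splits at higher $C$ may change an apex estimate by a
sample). Sensitivity/specificity are therefore monotone in $C$ at
one-event/one-bin granularity, which is what the test suite asserts.

## Seizure segmentation, classification, SE

The electrographic seizure start is defined as the moment the amplitude of a
spike train reaches twice the baseline. Operationally, a 2 s window sliding
in 0.25 s hops qualifies as ictal when it contains at least 3 supra-threshold
spike deflections (≥2× the background envelope) **and** its RMS reaches
twice the baseline RMS; the onset is the start of the first stretch of
qualifying windows sustained for 2 s. Because ictal activity is oscillatory,
"twice the baseline" is read on the RMS scale for the energy criterion
(`baseline_ref = "rms"`); a peak-envelope reading is available as
`baseline_ref = "envelope"`. The offset is the first subsequent time the RMS
stays below 1.5× baseline for 5 s — a hysteresis pair chosen because the
qualitative criterion ("EEG returns to normal") needs a declared convention.
Events closer than 10 s are merged. Window length, sustain, hysteresis and
merge gap are config-exposed; the defaults are robust at 512 Hz and are the
values used throughout the tests.

Classification combines channels and behaviour: CA3 intervals overlapping a
motor-cortex interval *and* carrying stage III–V are generalized; CA3-only
intervals with stage I–II are focal; conflicting combinations (CA3-only with
stage V, or synchronized with stage I) are flagged `"unclassified"` and
surfaced, never coerced. Synchrony means any temporal overlap — the cortical
channel typically joins with a delay, so no onset alignment is required.
Stage records may precede the estimated electrographic onset by up to 5 s
(`stage_lookback_s`), since segmentation onsets carry ~1–2 s estimation
error. SE is flagged on any single event or chain of events (gaps < 10 s)
spanning more than 1800 s; an SE chain counts as one event in the metrics.

The responsive-stimulation trigger simulator replays the same onset rule
causally: window statistics become available only when each window completes,
and the trigger fires when the sustained criterion is first confirmed. With
the generator's default 8 s onset ramp, simulated trigger latencies land in
the 3–5 s range, the same order as the few-second delays reported for
visually triggered stimulation in this preparation; we treat that as a
qualitative correspondence, not a calibration target.

## Session metrics and statistics

Per session we report focal/generalized counts, the latency of the first
focal seizure relative to the most recent preceding injection, total ictal
durations by class, inter-focal-seizure intervals (onset-to-onset by default,
offset-to-onset selectable) log-transformed in base 10 — intervals of
100–250 s map to log values of 2.0–2.4, matching the scale on which such
intervals are conventionally reported — and the IS rate over the 90-minute
session containing the first seizure. Sessions without focal seizures
contribute no latency value (excluded and counted, not imputed as a censored
maximum). Group×day cells are summarized as mean ± SEM with explicit
exclusion counts; single-session cells report no SEM.

Three tests cover the designs that arise:

* `pooled_t_from_summary()` — Student's pooled-variance two-sample t
  computed from each group's mean, SEM and n alone. With Day-1 focal counts
  of 8.9 ± 1.7 (n = 7) versus 25.1 ± 5.1 (n = 8), it gives t(13) = 2.84 —
  and df = 13 = 7 + 8 − 2 is itself evidence that the pooled (not Welch)
  convention is the right reconstruction of such reported contrasts. The
  same formula applied to the published log inter-seizure intervals
  (2.4 ± 0.1 vs 2.0 ± 0.1) yields ≈2.81 where 2.38 was reported; the rounded
  summaries do not determine the raw-data statistic, so that value is
  documented as non-recoverable rather than targeted.
* `paired_t_test()` — dependent-samples t for day contrasts.
* `mixed_rm_anova()` — the two-way split-plot decomposition (between-subject
  group tested against subjects-within-group; within-subject day and the
  interaction against the day×subject stratum), fitted via `aov()` with an
  `Error(subject/within)` term. No sphericity correction is applied, so a
  15-subject, 2-group, 3-day design reports the uncorrected df (2, 26) for
  day effects and (1, 13) for the group effect. The test suite checks the F
  statistics against an independent sums-of-squares implementation to
  1e-10.

Two-sided p-values are used throughout, and no multiple-testing correction
is applied across the seizure parameters — the analysis mirrors the field's
reporting convention; users comparing many metrics should adjust accordingly.

## What the generator emulates — and what it does not

`generate_session()` renders: stationary Gaussian background noise (pink
noise optional, to stress the detector's distributional assumption);
interictal spikes as biphasic pointed transients (triangular main lobe, 25%
undershoot) whose full width at half amplitude is the nominal duration,
placed by a thinned Poisson process at ≥2× the background envelope; seizures
as spike trains ramping linearly in rate (1→8 Hz) and amplitude (1→3×
envelope) over 8 s, sustained until an abrupt offset; generalized seizures
echoed on the motor-cortex channel after a configurable delay; and optional
125 Hz square-wave stimulation-artifact epochs. The annotated seizure onset
is placed where the ramping amplitude crosses 2× the envelope — the same
instant the segmenter's onset rule targets — with the sub-threshold build-up
rendered just before it; this makes onset-accuracy statements well-defined.

`generate_cohort()` draws per-session seizure counts and spike rates from
group×day distributions whose defaults reproduce the observed summary table
of the motivating experiment (Day-1 focal counts 8.9 ± 4.5 vs 25.1 ± 14.4 as
mean ± SD; days 2–3 near-equal across groups). Day-1 counts are drawn from a
normal truncated to ≥1: the injection protocol re-doses until convulsive
seizures appear, so every Day-1 session seizes, and a clamp-at-zero model
would put an artificial point mass at zero. Later days allow zeros
(sensitivity to the convulsant declines with repeated injections). IS-rate
distributions are not published at this granularity; the defaults (HFS
4→2/min, sham 8→4/min across days) are plausible for this preparation and
are stated here as the package's own choice. Under this model the
Monte-Carlo power of the pooled t on Day-1 focal counts at n = 7 vs 8 is
≈0.9, and its type-I error under the null configuration is nominal.

What the generator does **not** emulate: non-stationary drift, movement and
chewing artifacts, electrode pop, spindles or other physiological
transients, spike-wave morphology variation, postictal suppression, or any
biophysical network dynamics. Passing tests therefore demonstrate that the
pipeline implements its stated rules correctly and recovers truth under the
model's assumptions — not that it is robust to everything real recordings
contain. The pink-noise option deliberately violates the Gaussian-white
assumption and is the first robustness check a user should run.

## Numerical conventions and scale of the test problems

Time is seconds from session start; intervals are closed–open
`[onset, offset)`; events are sorted by onset. Signals travel as a CSV
dialect (`time_s, CA3_uV, MCX_uV`) with a strictly uniform timebase;
annotations as a typed event CSV (`spike`, `seizure`, `stage`, `injection`,
`hfs`) validated on read. Zero-variance baselines, empty calibration grids,
missing stage or injection annotations, incomplete repeated-measures tables
and overlapping schedules are rejected with messages naming the offending
input, not silently repaired. Degenerate ANOVA inputs (all values equal)
return F = 0 rather than 0/0.

The examples and tests run on sessions of 2–20 minutes with the full 512 Hz
machinery — long enough for stable baselines (60 s), dozens of spikes and
multiple seizures per session, short enough that the whole validation suite,
including 500-cohort Monte-Carlo calibrations, completes in a couple of
minutes. A full 90-minute session (2.7M samples per channel) runs through
the same code in a few seconds.

## A worked session

```{r session}
cfg <- generator_config(
  session_duration = 600, spike_rate = 6, spike_amplitude_factor = 3,
  seizure_schedule = data.frame(
    onset_s = c(250, 450), duration_s = c(40, 60),
    class = c("focal", "generalized"), stage = c("II", "IV"),
    generalization_delay_s = c(NA, 2)),
  seed = 7)
ses <- generate_session(cfg)

baseline <- estimate_baseline(ses$recording, c(0, 60), channel = "CA3")
baseline

truth <- annotation_events(ses$annotation, "spike")
cal <- calibrate_threshold(ses$recording, baseline, truth, channel = "CA3",
                           exclude = exclusion_intervals(ses$annotation))
cal
```

```{r segment}
ca3 <- segment_seizures(ses$recording, baseline, channel = "CA3")
mcx <- segment_seizures(ses$recording,
                        estimate_baseline(ses$recording, c(0, 60), channel = "MCX"),
                        channel = "MCX")
st <- annotation_events(ses$annotation, "stage")
seizures <- classify_seizures(ca3, mcx,
                              tibble::tibble(time_s = st$onset_s, stage = st$label))
seizures <- detect_status_epilepticus(seizures)
seizures

spikes <- detect_spikes(ses$recording, baseline,
                        detector_config(C = cal$chosen_C), channel = "CA3",
                        exclude = exclusion_intervals(ses$annotation, ca3))
compute_session_metrics(seizures, spikes, ses$annotation,
                        session_minutes = 10)
```

```{r plot, fig.height = 4}
autoplot(ses$recording, events = ca3)
plot_calibration(cal)
```

## The group analysis, end to end

```{r cohort}
co <- generate_cohort(c(hfs = 7, sham = 8), days = 3, seed = 1,
                      build_configs = FALSE)
summary_tab <- co |>
  rename(n_focal = n_focal_true) |>
  aggregate_day_metrics(metrics = "n_focal")
summary_tab

anova_fit <- mixed_rm_anova(co, n_focal_true, rat_id, day, group)
tidy(anova_fit)

d1 <- summary_tab |> filter(day == 1)
pooled_t_from_summary(d1$mean[d1$group == "hfs"], d1$sem[d1$group == "hfs"], 7,
                      d1$mean[d1$group == "sham"], d1$sem[d1$group == "sham"], 8)
```

## Known limitations

* The detection statistic compares $z^2$ against $C$ directly; if one
  prefers a threshold stated on the density or SD scale, the mapping is
  $\sqrt C$ SDs, but no other threshold convention is provided.
* Segmentation assumes a stationary baseline; slow drift inflates the RMS
  criterion and should be removed upstream (the package performs no
  filtering).
* Behavioural stages are consumed as annotations and never inferred from
  EEG; sessions lacking stage records cannot be classified.
* The responsive trigger is a simulation for latency studies; no hardware
  control is implied.
* Latencies are not treated as censored observations; sessions without
  seizures simply contribute no latency.
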