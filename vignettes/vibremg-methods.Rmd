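---
title: "Methods: quantifying antagonist sEMG modulation after focal muscle vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying antagonist sEMG modulation after focal muscle vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Focal muscle vibration (FMV) applied to an agonist muscle (here the biceps
brachii) is expected, through spinal reciprocal inhibition, to transiently
suppress the activity of its antagonist (the triceps brachii). `vibremg`
implements a fully non-invasive way to quantify that suppression from
surface EMG (sEMG) recorded during a standardized motor task: repeated
elbow flexion-extension at 60 beats per minute, one cycle per beat, with
the elbow angle tracked by an inertial sensor (the ROM signal).

The design is a two-session within-subject crossover. Each session
(control and FMV) starts with a baseline trial (`pre`); after five minutes
of rest (control) or vibration (FMV), seven one-minute follow-up trials
are recorded every five minutes (`post`, `post5`, ..., `post30`). The unit
of analysis is the **post/pre RMS ratio**: each follow-up trial's total
RMS amplitude divided by the same session's baseline RMS. Ratios are
unit-free, cancel electrode placement and tissue-conductivity factors that
differ between sessions, and make "no change" exactly 1.

## Signal chain

Each trial is processed by a fixed chain; every stage is an exported
function so the chain can be inspected step by step.

1. **Band-pass filter** (`bandpass_filter`). Order-4 Butterworth, 20-450 Hz
   passband, applied forward and backward so the net phase response is zero
   and the EMG envelope stays aligned with the joint-angle timeline. The
   signal is reflected at both ends before filtering to control edge
   transients. Nothing requires the raw signal to be unfiltered: the stage
   is idempotent-safe, so exports that were already band-passed on-device
   pass through essentially unchanged.
2. **Rectification** (`rectify`). Full-wave (absolute value).
3. **RMS envelope** (`rms_envelope`). Root-mean-square over consecutive
   *non-overlapping* 0.25-s windows, giving an envelope at 4 Hz. We read
   the "sliding window" of standard practice as non-overlapping because
   that is the only interpretation consistent with a 4 Hz effective
   envelope rate from 1024 Hz input; overlapping windows would preserve
   the raw rate. A trailing partial window is discarded rather than
   zero-padded, which would bias the final sample downward.
4. **Activation threshold** (`estimate_threshold`, `apply_threshold`).
   Movement onset is detected from the ROM signal (below). The minimum
   envelope value before onset is located (first occurrence on ties), and
   a window of up to 60 envelope samples is centred on it. The threshold
   is the window mean plus three population standard deviations
   (`ddof = 0`); it is subtracted from the whole envelope and only
   suprathreshold values are kept. Sub-threshold samples are set to zero
   but *kept on the timeline*, so cycle windows remain time-aligned.

   Two windowing details matter. First, the window is clipped to the
   pre-onset segment, not just to the signal bounds: 60 points at 4 Hz is
   15 s, and with a lead-in of a few seconds a window clipped only at the
   array edges would reach deep into the movement, contaminating the
   "noise" statistics with bursts and producing thresholds an order of
   magnitude above the noise floor. Restricting the window to data before
   movement onset is the reading consistent with the procedure's purpose
   (characterising resting noise). Second, the window nominally operates
   on the 4 Hz envelope; `window_points` is configurable for variants of
   the procedure that use a higher-rate processed signal.
5. **Cycle segmentation** (`detect_cycles`, `select_central`). Flexion-
   extension cycles are delimited by successive ROM maxima (peak flexion),
   found by prominence-based peak detection: peaks must be at least half a
   nominal cycle apart and have topographic prominence of at least 25% of
   the angle range *and* at least 5 degrees. The absolute floor encodes
   that an oscillation of a few degrees is not an elbow movement, so flat
   or noise-only traces fail loudly instead of yielding phantom cycles.
   From the detected cycles the 10 consecutive central ones are selected
   (block start `floor((n - k) / 2)`, favouring the earlier block), which
   avoids the transitional movements at the start and end of a trial.
   Valley-anchored segmentation is available (`anchor = "valley"`); it
   shifts boundaries by half a cycle and does not change the total-RMS
   statistic materially because the selected span covers whole cycles.
6. **Total RMS and ratio** (`total_rms`, `build_ratio_table`). The default
   statistic pools every corrected-envelope sample whose window start lies
   in the union of the selected cycles and takes one RMS over the pooled
   samples, zeros included — an energy measure over the task window. Two
   alternatives are exposed because the thresholding step admits both
   readings: `active_only` (suprathreshold samples only) and
   `per_cycle_mean` (mean of per-cycle RMS values).

**Movement onset** is the earliest time at which the absolute angular
speed (central difference of ROM) stays above 5 deg/s for at least 0.5 s.
The speed trace is rectified *before* light smoothing (0.1 s moving
average): smoothing the signed speed first would cut the sustained run at
every speed zero-crossing of a cyclic movement, which occurs twice per
cycle. The ROM signal is used because it is the only kinematic channel
recorded; 5 deg/s sustained for half a second separates instrument drift
from intentional movement at this task's speeds (peak speed ~280 deg/s).

## Statistical analysis

Two complementary families are computed from the ratio table, each
Benjamini-Hochberg (BH) adjusted within its own family of seven tests.

**Within-session contrasts** (`fit_intragroup`). A linear mixed-effects
model with one fixed effect per follow-up point and a random intercept per
participant, fitted by REML through `lme4`. The default response is
`log(ratio)`: on the log scale "ratio = 1" becomes "coefficient = 0",
multiplicative subject effects become additive, and the model-based ratio
estimate is `exp(coefficient)`. Summary tables still report means and SDs
on the raw ratio scale. A raw-scale variant (`scale = "raw"`, coefficients
tested against 1) is provided since either parameterisation is defensible;
the two agree on the direction of clear effects and differ only near the
null. Coefficients are tested with Wald z by default — the convention of
the mixed-model implementations commonly used for this analysis — which is
known to be mildly anticonservative at n = 30 (roughly a 0.06 realised
family rate at nominal 0.05 in our null simulations' neighbourhood);
`df_method = "satterthwaite"` switches to Satterthwaite t tests via
`lmerTest` for users who want exact-size small-sample behaviour. The
mixed model handles missing or unbalanced rows natively, which is why
trial-level failures are logged and skipped rather than fatal.

**Between-session comparisons** (`compare_groups`). At each follow-up
point, paired differences (FMV minus control) across participants with
both sessions are tested against zero: Shapiro-Wilk on the differences
gates between a paired t-test (normality not rejected at 0.05) and a
two-sided Wilcoxon signed-rank test (zero differences dropped, normal
approximation). The paired t has n − 1 degrees of freedom. All-zero
difference vectors are reported as degenerate with p = 1 and a warning.

**BH adjustment** (`benjamini_hochberg`) is implemented in the package as
the standard step-up rule — `adjusted_(i) = min_{j >= i} m p_(j) / j`,
capped at 1 — and is verified in the tests against both a brute-force
evaluation of that definition and `stats::p.adjust`.

## The synthetic-study generator

`simulate_study` generates complete crossover studies so the whole
pipeline is testable without any recordings. Its defaults encode the
protocol conditions: 30 participants, 1024 Hz, 60-s trials, 60 bpm,
sinusoidal ROM spanning 90 degrees, a 3-s quiescent lead-in, and an FMV
effect profile (0.84, 0.80, 0.86, 0.84, 0.85, 0.97, 0.93 at 0-30 min)
with the control profile at 1 — attenuation for ~20 minutes, then return
toward baseline.

The EMG model is amplitude-modulated noise: a 20-450 Hz band-limited
Gaussian carrier (so the band-pass stage is non-trivial) multiplied by a
raised-cosine burst occupying 40% of each cycle, centred mid-extension
because the triceps is the elbow extensor, plus white instrumentation
noise (SD 8 µV) everywhere including the lead-in. Burst gain is
`80 µV * exp(subject effect) * exp(trial jitter) * true ratio`, with
between-subject log-amplitude SD 0.3 and trial-to-trial jitter SD 0.1.
The subject effect is drawn once per participant and shared across both
sessions (a true crossover). Angle noise is smooth drift (SD 0.5 degrees)
rather than white noise, matching how IMU angle estimates actually
wander; jittery angle noise would trip the onset-speed criterion during
rest, which no real resting arm does. All randomness flows from one seed;
the same seed reproduces every number, and on-disk study trees are
byte-identical across runs.

Two deliberate limitations of the signal-level generator: the subject
amplitude effect multiplies baseline and follow-up trials alike, so it
cancels in the ratio — simulated ratio spreads (~0.15) are tighter than
the ~0.3 SDs typical of real studies of this design, which reflect
between-subject heterogeneity in *responsiveness*. For Monte-Carlo work
on the statistical families at realistic spreads, `simulate_ratio_table`
draws ratios directly from the generative model the mixed model assumes
(log-ratio = log true ratio + subject intercept (SD 0.3) + trial noise
(SD 0.15), total ratio SD ~0.33). And the generator contains no
motor-unit structure, fatigue, electrode-lift artifacts or cross-talk:
passing tests demonstrate that the pipeline recovers what this model
injects, not that it is robust to everything real electrodes produce.

The threshold-subtraction step biases recovered ratios slightly toward
zero (subtracting a fixed noise threshold from both numerator and
denominator shrinks an attenuated trial proportionally more); at the
default noise-to-burst ratio this bias is about 0.02-0.03 ratio units,
visible in the parameter-recovery simulations and well inside their 0.05
acceptance band. It is a property of the correction procedure itself, not
of this implementation.

## Numerical and testing choices

- Half-open time intervals `[a, b)` and 0-based sample offsets in the
  threshold metadata; envelope sample `k` (1-based) covers raw time
  `[(k-1), k) * 0.25` s, and a sample belongs to a cycle if its window
  start lies in the cycle interval.
- Argmin ties resolve to the first occurrence; the central-cycle block
  resolves even/odd ambiguity toward the earlier block.
- Degenerate inputs fail as classed errors (`vibremg_data_error`,
  `vibremg_segmentation_error`, ...) so the study-level driver can log
  and continue; a session with identical responses yields p = 1 rather
  than a crash.
- The zero-phase filter is two passes of a compiled direct-form-II
  transposed kernel with reflective padding; it matches the reference
  `signal::filter` composition to ~3e-13 and makes study-scale
  simulation practical on one CPU.
- Monte-Carlo problem sizes in the test suite: 30 full signal-level
  replicates of the complete 30-participant study for parameter recovery
  (the Monte-Carlo error of the replicate-averaged means, ~0.006, is an
  order of magnitude below the 0.05 acceptance band), and 200 ratio-level
  replicates for the null false-positive-rate check. Unit tests use
  shorter (12-20 s) trials; every fixture is generated in code.

## Worked example

```{r, eval = FALSE}
library(vibremg)

cfg <- sim_config(n_participants = 30, seed = 7)
study <- simulate_study(cfg)          # in memory; out_dir writes CSV + YAML
res <- run_all(pipeline_config(seed = 7), study = study)
res$report                            # per-session contrasts + paired tests
plot_ratio_boxplot(res$ratios)        # ratio evolution over the follow-up
```

## Known limitations

- MVC normalization is deliberately absent: the ratio statistic is the
  normalization, by design of the underlying protocol.
- Wald z intragroup tests are mildly liberal at small n (switch to
  `df_method = "satterthwaite"` if that matters for your use).
- The onset criterion and the 5-degree prominence floor assume limb-scale
  joint movement; very slow or very small-amplitude tasks need different
  `speed_thresh_deg_s` / `min_prominence_deg`.
- Frequency-domain and motor-unit-level analyses are out of scope.
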