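---
title: "Characterizing attention-modulated scanning access from a single-channel EEG sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing attention-modulated scanning access from a single-channel EEG sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attenscan)
```

## The problem

Some people with severe motor disabilities cannot operate a physical
switch, an eye tracker, or a gaze-dependent brain-computer interface.
One alternative is to let them *select by attending*: a communication
board highlights its pictograms one at a time with period `t_scan`, and
the user raises their mental attention above a threshold — as estimated
at 1 Hz by a one-channel forehead (Fp1) EEG headset — when the wanted
pictogram lights up, holding it there for a dwell window of `t_w`
seconds, then releasing it before the next pictogram is highlighted.

`attenscan` implements the complete computational chain needed to decide
whether, and with which parameters, a given user can operate such a
board:

1. **Artifact screening** of the raw 512 Hz signal, one epoch per second.
2. **Trial metrics** on the 1 Hz attention stream: successful score,
   initial time, sustained time.
3. **Band statistics**: per-subject rank-sum comparisons of the power
   bands between attentional states.
4. **Classification** of the attentional state with a linear
   discriminant and stratified k-fold cross-validation.
5. **Access model**: dwell-window search under three feasibility
   constraints, and the resulting information transfer rate.
6. A **synthetic-data generator** that emulates the recording protocol,
   because the original recordings were never deposited.

## The recording protocol and its synthetic stand-in

The protocol the generator emulates is: per subject, 5 sessions of 14
one-minute trials; each trial has a 30 s task half followed by a 30 s
rest half; odd trials ask for high attention, even trials for low
attention; the sensor emits attention and meditation indicators (0-100)
and 8 (configurably 9) spectral power bands at 1 Hz, plus a
contact-quality flag.

The generator is deliberately phenomenological — it reproduces the
*statistical structure the analysis assumes*, not the electrophysiology:

- **Attention indicator.** A clipped AR(1) process around a target mean.
  The target starts each task half at the opposite class mean and
  switches to the trial's class mean after a latency drawn from an
  exponential distribution (mean `tau_on` or `tau_off`). The study
  reports only empirical mean latencies, so any unimodal positive
  latency law is consistent with them; the exponential was chosen as the
  one-parameter option. The switch takes effect at the sample whose
  one-second reporting window contains the latency's midpoint
  (`round(latency)`), which makes the detected crossing time an almost
  unbiased estimate of `tau + 1` — the `+ 1` because a crossing at the
  very first sample is reported as 1 s.
- **Clipping, not reflection**, to [0, 100] after the AR(1) update: the
  indicator is a bounded percentage, and a saturating subject genuinely
  sits at the bound.
- **Band powers.** Log-normal per second, with a signed per-band
  log-scale shift in attention trials (`band_shift`). The default
  profile encodes the direction pattern the analysis should recover:
  delta and the theta/beta ratio lower under attention, gamma higher.
- **Rest halves** are generated (around the midpoint of the class means)
  but excluded from every analysis; they exist so that files and
  alignment behave like real sessions.
- **Raw epochs.** Clean epochs are AR(1)-filtered noise (a 1/f-like
  spectrum at EEG-scale amplitude, ~50 ADC counts SD in a 12-bit range).
  A blink adds one ~400 ms biphasic deflection; EMG a ~300 ms broadband
  burst; motion a large slow swing plus broadband noise. The same seed
  produces the same clean background for all kinds, so artifact epochs
  are paired with clean counterparts for testing.

What the generator does **not** emulate: volume conduction, true EEG
spectra and their nonstationarity, the proprietary algorithm behind the
attention indicator, circadian or fatigue drifts across sessions, and
any correlation between the attention indicator and the band powers
beyond their shared class label. Consequently, passing tests show that
the *pipeline* recovers what it assumes — not that the sensor measures
attention.

## Artifact screening

Each one-second epoch (512 samples) is summarized by two features:
`MinMax`, the peak-to-peak amplitude, and `ESF`, the energy of the
residual after subtracting a Savitzky-Golay smoothed epoch (local
least-squares quadratic, window 35). Blinks raise `MinMax` while leaving
the high-frequency residual small; muscle bursts raise `ESF`; motion
raises both. Classification uses closed-interval threshold boxes: clean
box first, then blink, everything else `artifact_other`. Boxes are
calibrated from labeled epochs as the `[q, 1-q]` feature quantiles
(default `q = 0.01`), which keeps the clean box conservative.

Numerical choices: the Savitzky-Golay smoother uses **mirror padding**
at the epoch edges; the tested contract is the interior behavior, where
the filter reproduces polynomials up to degree 2 exactly. Blink epochs
are detected separately but their seconds are still invalid — only
artifact-free seconds feed the analysis. A second is valid iff the
contact-quality flag is 0 *and* (when raw epochs are available) its
epoch is labeled clean; gating can therefore only shrink validity.

## Trial metrics

With threshold `h` (default 50%), on the valid seconds of a task half:

- **Successful score (SS)**: percentage of valid seconds strictly on the
  goal side (`> h` in attention trials, `< h` in non-attention ones).
  Equality counts as failure, because the task is stated as "above" /
  "below".
- **Initial time**: 0-based time of the first valid goal-side second,
  plus one (an immediate crossing is 1 s).
- **Sustained time**: the mean length of maximal goal-side runs. The
  alternative reading (longest run) was rejected because the reported
  per-subject values pair with small standard errors across trials,
  which fits a mean-of-runs statistic.

Outliers are removed per signal and trial with the interquartile rule
(keep `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, type-7 quartiles) before
averaging. The filter is applied **once**, as in the procedure it
implements; a second application can remove further points (the
post-filter quartiles shrink), so no fixed-point property is claimed
beyond the filtered example set.

Per-trial features for classification: `set1` is the filtered mean
attention; `set2` adds the theta/beta ratio, computed as
mean(theta)/mean(beta) (ratio of filtered means, since features are
defined on trial averages — not the mean of per-second ratios); `set3`
is attention plus all raw band means, meditation excluded (10 values
with 9 bands). The split sensor bands are summed to the five canonical
bands for the statistics.

## Band statistics

Per subject, attention and non-attention trial means (70 rows for the
full protocol) are compared with a two-sided Mann-Whitney-Wilcoxon test
per variable: attention, delta, theta, alpha, beta, gamma, theta/beta.
Mid-ranks handle ties; the exact null distribution is used when both
samples have at most 20 observations and no ties, otherwise the normal
approximation with continuity and tie correction (the switch at 20 is
standard practice). **No multiple-testing correction is applied** across
the seven variables — the raw per-variable p-values are reported, which
is how the original per-subject tables are laid out; users comparing
many subjects and variables should correct downstream. Effect directions
are reported only where the test is significant.

Survey ratings (three questions, 3-point scale, one response per
session) are averaged per subject across sessions and then per group
across subjects: the group mean is the mean of subject means, which is
what the published group rows print.

## Classification

The linear discriminant uses the pooled within-class covariance with
maximum-likelihood normalization (divide by n, which makes the fit
exactly invariant to duplicating the training set) and equal priors, so
the decision threshold is the midpoint of the projected class means.
When the covariance is singular or its condition number exceeds 1e8 —
routine when ten-dimensional `set3` features are fit from six trials — a
ridge `lambda = 1e-3 * trace(S)/d` is added; with zero variance
altogether the direction degenerates gracefully to the mean difference.
The orientation is fixed so the attention class projects higher.

Cross-validation is stratified 4-fold with a seeded fold assignment;
accuracy is pooled over held-out folds and the AUC is computed from the
pooled held-out scores with the rank statistic (mid-ranks on ties), not
as a mean of per-fold AUCs — pooling is stable at 70 trials. Note that
pooled AUC is not invariant to per-fold affine score offsets; accuracy
is.

## The access model

For a candidate dwell window `t_w` (grid: integer seconds 2-15, capped
because the cohort-average sustained time is about 14 s), each session
is evaluated with a balanced 6/4/4 train/validation/test split redrawn
10 times:

- Training features come from the **first** `t_w` seconds of each
  training trial.
- Validation and test trials mirror online use: per-second features are
  projected in order and the first supra-threshold second starts the
  `t_w` window (truncated at trial end); a trial that never crosses is
  predicted non-attention.
- `t_on` / `t_off` are the times to the first supra-/sub-threshold
  projected second in attention / non-attention validation trials.
  Trials that never cross are excluded from the statistics but counted.
  Latencies are pooled across repeats and sessions before taking mean
  and SD: two validation trials per class per repeat are too few for a
  stable SD, and the SD feeds the feasibility constraints.
- `Np` is the mean number of maximal supra-threshold runs of length at
  least `t_w` in non-attention validation trials; it is non-increasing
  in `t_w` by construction.

The scan ascends the grid and stops at the first `t_w` satisfying both
constraints (strict inequalities):
`t_w > mean(t_off) + 1.64 sd(t_off)` and
`Np (N_icons - 1) t_scan < 30 s`, with
`t_scan = mean(t_on) + 1.64 sd(t_on) + t_w`. The **validation** set
drives the choice (its latencies and pulse counts enter the
constraints); the **test** set supplies the reported accuracy at the
chosen window. If no grid point is feasible the largest window is
reported with a feasibility marker set to false, matching the published
convention of printing the 15 s row with an asterisk.

The information transfer rate uses the Wolpaw bits-per-selection for an
N-choice channel (`N = 2`: attention high/low),
`B = log2 N + P log2 P + (1-P) log2((1-P)/(N-1))`, at the test accuracy
and with the dwell window as the selection time; accuracies at or below
chance clamp to 0 bits/min. A perfect binary selection every 2 s is
therefore 30 bits/min.

A null (chance-level) synthetic subject can still come out *feasible*:
random threshold crossings make its off-latency short and its long
supra-threshold runs rare, so the constraints — which measure timing,
not discriminability — may hold while accuracy stays near 50%. This is
why the report couples the feasibility marker with the accuracy and ITR
columns rather than treating feasibility alone as usability.

## Reference tables

The original study's recordings were never deposited. The package
therefore ships the study's *published per-participant summary tables*
(access parameters with latencies, trial summaries, survey ratings) as
plain CSV under `inst/extdata/`, exposed via `study_access_table()`,
`study_trial_summary()` and `study_survey()`. The report operations
(`access_report_summary()`, `tscan_min()`, `survey_group_means()`)
recompute the published group-level arithmetic from these per-subject
cells; everything else in the package is validated on synthetic cohorts.

## Problem sizes and determinism

The test suite and the acceptance script run full 5-session synthetic
protocols (70 trials per subject), 100-replicate calibration checks for
the classifier, a 1000-replicate size check for the rank-sum test, and
200 labeled epochs for the screening bounds — sizes chosen so each
statistical check has conventional power while the whole suite stays
interactive. Every random draw flows from explicit integer seeds;
regeneration is bit-identical, and package functions restore the
caller's RNG state.

## Known limitations

- The generator's step-plus-AR(1) attention model cannot represent
  gradual ramps, anticipation before trial onset, or fatigue trends.
- The attention indicator itself is a proprietary black box; this
  package treats it as ground truth input and cannot validate it.
- Threshold-box screening assumes artifacts separate in the
  (MinMax, ESF) plane; overlapping artifact types degrade to
  `artifact_other` rather than being resolved.
- Between-session nonstationarity is handled only by evaluating
  sessions separately and averaging, as in the original protocol.
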