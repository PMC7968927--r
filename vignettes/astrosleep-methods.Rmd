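---
title: "Methods: linking astrocyte calcium events to sleep electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking astrocyte calcium events to sleep electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(astrosleep)
```

## What the package computes

`astrosleep` implements an analysis pipeline for experiments that record
cortical astrocyte Ca²⁺ events (an event table in the style of event-based
detectors such as AQuA: one row per event with an onset time and ~20
morphology/kinetics features) simultaneously with local field potential
(LFP), EEG, EMG and locomotion in naturally sleeping head-fixed mice.
The pipeline covers:

1. **Sleep scoring** — threshold rules on z-scored spectral and EMG
   features per 5 s epoch, period segmentation, and subdivision of wake by
   locomotion.
2. **Slow-wave analysis** — detection of slow-wave candidates at
   positive-to-negative zero crossings of the 0.1–4 Hz filtered signal
   during NREM, verification of UP/DOWN polarity by nested high-gamma, and
   percentile/duration classification into *slow oscillations* (large,
   global) versus *delta waves* (smaller, local).
3. **Ca²⁺ event statistics** — event rate versus slow-wave activity (SWA,
   0.5–4 Hz power) and behavioral state, pre-transition dynamics, tertile
   analysis, cumulative counts after an injection, and PCA of the
   20 event features with ECDF/KS/Wilcoxon machinery.
4. **Event-triggered coupling** — event-triggered SWA averages and
   modulation, and event-aligned Welch magnitude-squared coherence between
   two channels with random-aligned controls and Bonferroni-corrected
   per-frequency tests.
5. **Condition comparison** — per-session summaries (occupancy,
   transitions, bouts, SWA distributions) and paired saline/CNO contrasts
   for chemogenetic (DREADD) experiments.

Every stage is exercised against a bundled synthetic-session generator
with known ground truth, so the full pipeline is testable without any
recorded data.

## Scoring model and thresholds

Scoring operates on 5 s epochs from a 10 s moving-window spectrogram
(5 s step, Hann taper). The features are the slow-wave ratio (0.5–4 Hz
power / 8–20 Hz power) and theta power (6–10 Hz), each z-scored across the
session's frames, the mean absolute z-scored EMG per 5 s bin (z-scored
across bins), and a locomotion flag. The rules, all configurable and in
SD units of the frame distribution:

* **NREM**: slow-wave ratio > 0.5 SD, stationary, EMG < 5 SD.
* **REM** (only if not NREM): theta > 0.25 SD, stationary, EMG < 0.4 SD.
* everything else is **wake**.

Consecutive same-state epochs form periods; sleep periods shorter than
15 s (configurable; 30 s for transition analyses) are reassigned to wake,
where a "sleep period" is a maximal run of sleep epochs (NREM or REM): a
brief REM stretch inside a long NREM period does not count as a short
sleep period.
Wake periods are subdivided at 1 s resolution into locomotory and
stationary sub-periods; the first 10 s of a stationary sub-period that
follows locomotion is excluded (Ca²⁺ bursts outlast locomotion), and
stationary sub-periods shorter than 15 s are excluded from substate
analyses.

Because the thresholds are expressed in SDs of the *session's* feature
distribution, their effective position depends on state occupancy: a state
that dominates a session sits near the distribution mean by construction.
This is an inherent property of the rule set, not of the implementation,
and it shapes several generator design choices below.

## Slow-wave detection and classification

The signal is filtered with a zero-phase second-order high-pass at 0.1 Hz
followed by a zero-phase fourth-order low-pass at 4 Hz. Every
positive-to-negative zero crossing during NREM yields a candidate with a
preceding peak and a following trough. Because gamma rhythms nest in
cortical UP states, 80–100 Hz amplitude is compared between candidate
peaks and troughs; if peaks carry more high-gamma than troughs (strict
inequality) the signal polarity is inverted and detection re-run.

Percentile gates are computed within each recording (peaks and troughs
ranked separately, troughs on signed values):

* slow oscillation: peak > 85th percentile, trough < 40th percentile,
  peak-to-trough duration 150–500 ms;
* delta wave: peak < 85th percentile, trough < 40th percentile,
  duration > 100 ms.

Choices the procedure leaves open, resolved here: the high-gamma
comparison window is ±50 ms around each extremum; classification refuses
recordings with fewer than 20 candidates (percentiles unstable); no upper
duration bound is applied to delta waves; filtering is zero-phase even
though a causal filter would also satisfy the letter of the procedure,
because phase distortion would bias the millisecond duration gates.
Signal boundaries act as implicit flanking crossings so a wave at the
very start or end of a record is still measured.

A numerical note: a direct fourth-order Butterworth *bandpass* design for
0.5–4 Hz at 1 kHz is unstable in double precision (poles marginally
outside the unit circle). Bandpass filtering therefore falls back to an
equivalent, well-conditioned high-pass + low-pass cascade whenever the
direct design is unstable.

## Event statistics

Event counting uses event *onsets* throughout. Rate–SWA coupling uses
2-min bins (Pearson). State rates divide events among NREM, stationary
wake and locomotory wake by period membership, with rank-sum tests on
per-period rates. Transition profiles normalize each period's final-30 s
histogram by the period's total event count before averaging, so
high-rate periods do not dominate. The tertile metric for a period split
into three equal bins is (third-bin count − mean of the first two); the
symmetric two-bin baseline is robust to period-length variation, and the
paired test compares the third bin against that baseline.

PCA standardizes the 20 features before the eigendecomposition (they
carry incommensurate units: µm², s, dF/F). Constant columns are dropped
with a warning and zero-padded in the loadings. State comparisons pool
event scores across animals per state (two-sample KS per component);
condition effects are quantified per mouse as the KS distance between
saline and CNO score distributions within each state, compared between
sleep and wake across mice by Wilcoxon signed-rank.

## Event-triggered SWA and coherence

The instantaneous SWA trace is the 0.5–4 Hz band power in a **0.5 s
moving window sampled every 0.25 s**, z-scored per session. A 1 s window
was considered and rejected: the event-locked SWA structure of interest
is a dip-then-rise spanning ±2 s with a sharp sign change at the event
onset, and a 1 s window smears that transition across neighboring 0.25 s
lags, biasing per-lag estimates. The 0.5 s window halves the smearing at
the cost of a noisier trace; the extra noise averages out across events
in the event-triggered average (ETA).

Coherence uses Welch's averaged periodogram with a Hann window and a
1024-sample FFT inside a 1.5 s window following each alignment point. At
1 kHz that window holds two overlapping segments (anchored at the window's
start and end), so the estimator is strongly biased upward under
independence: the median magnitude-squared coherence of independent white
noise under this segmentation is `COHERENCE_NULL_BIAS` (0.516), with
`COHERENCE_NULL_CEILING` (0.55) an upper bound on per-frequency medians;
both were established by long-run simulation, as was the shared-tone
reference `COHERENCE_SHARED_TONE_REF` (0.998, the 10⁵-window Monte-Carlo
median at the tone bin for a shared 7 Hz tone plus independent equal-power
noise). The bias is why every event-aligned spectrum is compared against a
random-aligned control with the *same* estimator rather than against zero.

For transition-proximity binning, alignment points are binned by time to
the next sleep-to-wake transition: a truncated most-proximal bin
(−0.5..0 s) followed by 2 s bins. Windows in the proximal bin extend past
the transition into wake — empirically this *lowers* their coherence when
the coupled component is sleep-specific — so the packaged
proximal-vs-distal contrast excludes that truncated bin.

## The synthetic session generator

The generator defines the study conditions under which the pipeline is
validated. Defaults (a 60-minute session at 1 kHz) were chosen once to be
realistic for ZT 2–5 head-fixed recordings while possessing the
statistical structure the analysis assumes:

* **States**: semi-Markov bouts (exponential, truncated below at a 10 s
  minimum and above at four times the state mean — untempered exponential
  tails occasionally produce sessions so state-imbalanced that fixed-SD
  scoring gates sit inside the majority class) with means NREM 110 s,
  REM 60 s, wake 190 s, giving ≈ 35% NREM — on the
  low side of natural occupancy, deliberately: with z-scored thresholding,
  an NREM fraction approaching one half pushes the NREM feature cluster
  toward the fixed 0.5 SD gate (its z-position is bounded by
  √((1−p)/p) for occupancy p), and scoring of *any* data, real or
  synthetic, degrades there.
* **NREM slow activity** is a continuous train of biphasic cycles
  (positive half-sine peak, then negative trough): labeled slow
  oscillations (17/min of NREM; peak 2.4 ± 0.15 z) and delta waves
  (29/min; peak 1.15 ± 0.12 z) interleaved with low-amplitude background
  cycles that fill the remaining NREM time. Class labels are
  quota-interleaved (each cycle takes the class with the largest running
  deficit) so every short window has near-exact class composition and
  window-to-window slow power is stable, emulating the quasi-stationary
  depth of consolidated NREM. The class shares (≈ 15% / 26% / 59% of
  candidates) are chosen so the 85th-percentile peak gate and the
  40th-percentile trough gate fall inside the amplitude gaps between
  classes: with per-recording percentile gates, class proportions and
  detectability are one design decision, not two. The wave rates are
  consequently higher than typical in vivo estimates; this trades surface
  realism for an unambiguous ground truth.
* **Rhythmic bands** (theta ≈ 7 Hz; an NREM spindle-band rhythm ≈ 13 Hz)
  are amplitude-stable wandering tones rather than broadband noise:
  rhythms have no spectral skirts leaking into the 8–20 Hz denominator of
  the slow-wave ratio and no estimator chi-noise, which the fixed SD
  gates need to remain reliable. Wake theta (0.4–0.5 power units) sits
  below the session mean, NREM theta (2.0) well above, and REM (2.8)
  highest, so the REM theta gate (+0.25 SD) excludes wake at any
  plausible occupancy, and an NREM epoch that narrowly misses the
  ratio gate falls to REM — still sleep — rather than fragmenting a
  sleep period with spurious wake. The wave train is low-passed at 5 Hz
  before mixing (half-sine cycles carry harmonics into the theta band),
  and the 1/f floor spans 20–70 Hz only, because tone-noise cross-terms
  inside a scored band inflate its measured power variance.
* **High gamma** (80–100 Hz) is amplitude-modulated by the UP (trough)
  half-cycles with nesting depth 3; the floor stops at 70 Hz so the
  80–100 Hz band carries only the nested component.
* **Ca²⁺ events** are an inhomogeneous Poisson process with rates 20
  (NREM and REM), 40 (stationary wake) and 80 (locomotory wake)
  events/min — event-based detectors report tens of events per minute in
  a cortical field of view — a ±50% linear ramp over the final 30 s of
  sleep (up) and wake (down), and a condition-dependent rate profile.
* **SWA coupling kernel**: a −/+ plateau drive (dip before, rise after
  each event, ±2 s) modulates slow-band power multiplicatively. The gain
  is calibrated so the kernel amplitude is expressed in z-units of the
  *measured* SWA trace, using two constants measured once by long-run
  simulation: the estimator's relative variance (`SWA_EST_RELVAR`) and a
  residual-attenuation trim (`KERNEL_GAIN_TRIM`). The drive is sharpened
  at the transition and extended 0.375 s past the nominal support to
  compensate for the estimator's finite window, so the ETA recovers the
  boxcar kernel at every 0.25 s lag. The calibration identity is exact
  for single-state sessions; in mixed-state sessions between-state
  variance additionally attenuates the realized modulation, so kernel
  round-trip experiments use single-state (stationary wake)
  configurations. The default kernel amplitude is a gentle 0.05 z.
* **EEG** shares the slow-oscillation cycles with the LFP at full
  amplitude and omits delta waves entirely, encoding the local (delta)
  versus global (slow oscillation) dichotomy as testable ground truth;
  an optional shared 2–12 Hz component with a pre-transition amplitude
  ramp, and optional event-locked shared tone bursts, provide ground
  truth for the coherence analyses.
* **Event features**: 20-dimensional Gaussians per state under a
  three-factor correlation model (spatial / temporal / amplitude groups),
  so the leading PCs are interpretable and ~5 PCs carry ~70% of the
  variance. Locomotory events are larger and longer; sleep and stationary
  wake differ by a modest (0.35 SD) multi-feature shift.
* **Conditions**: `condition_gi()` (event rate ×1.6, delta amplitude
  ×1.2, slow oscillations ×1.05, transitions unchanged, a sleep-specific
  feature shift) and `condition_gq()` (a 2.5× rate surge for 8 min, then
  ×0.03 suppression; NREM-exit rate ÷2.8 and wake-exit rate ÷2, REM
  untouched). The asymmetric Gq scaling is deliberate: scaling both exit
  rates equally leaves expected occupancy unchanged and could not produce
  the joint signature this condition must show — more sleep *and* fewer
  transitions in both directions. Amplitude multipliers scale the drawn
  amplitudes under common random numbers, so paired conditions from the
  same seed differ exactly and only by the injected effect.

Same seed ⇒ byte-identical output; paired conditions share bout-level,
wave-level and event-level draws (common random numbers), which is what
makes ten-seed paired sign-recovery experiments sharp.

### What the generator does not emulate

Real recordings have non-Gaussian artifacts, non-stationary drift,
imperfect state boundaries (transitional epochs), spindles and
K-complexes, Ca²⁺ event waveform overlap, and feature distributions far
from Gaussian. Passing round-trip tests shows the pipeline recovers known
structure under its own assumptions; it does not certify performance on
any particular real dataset.

## Problem sizes used by the test-suite experiments

The validation experiments are sized for precision, not maximal scale:
scoring and wave recovery pool 20 default 60-min sessions at 250 Hz (all
analysis bands lie below 100 Hz, so 250 Hz is spectrally equivalent for
these checks and four times cheaper than 1 kHz); the kernel round-trip
averages three 500-event sessions (the per-lag SEM of a single 500-event
ETA is ≈ 0.04 z, so replicate averaging is needed for a ±0.1 z per-lag
check to reflect bias rather than sampling noise); correlation and
tertile experiments use 100 seeds at 20-min and 2.5-hour sessions
respectively (the tertile effect accumulates over sleep periods, and
2.5 h matches the length of the recordings this analysis style is used
on); condition contrasts use 10 paired seeds at 60 min (Gi) and 2 h (Gq,
matching the long post-injection suppression epoch such experiments
analyze).

## Known limitations

* The scoring thresholds are fixed SD rules; no per-animal tuning or ML
  scoring is provided, and accuracy degrades when one state dominates a
  session (see above).
* The coherence estimator with a 1.5 s window is strongly biased; only
  contrasts against the matched random-aligned control are meaningful,
  never absolute coherence values.
* Day-wise pooled z-scoring is implemented as pooling over an explicit
  session group; aligning groups with recording days is the caller's
  responsibility.
* REM is scored and reported but excluded from slow-wave and most Ca²⁺
  state analyses, which contrast NREM with wake substates.
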