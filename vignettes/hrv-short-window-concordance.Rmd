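---
title: "Ultra-short-term HRV concordance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-short-term HRV concordance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hrvconcord)
```

## The question and the analysis design

Short-term heart rate variability (HRV) is conventionally computed on
5-minute artifact-free stretches of beat-to-beat intervals (BBIs). Wearable
devices, especially wrist photoplethysmography, struggle to deliver five
continuous clean minutes, which motivates the *ultra-short-term* question:
how faithfully does a 1-minute window reproduce the 5-minute value of each
standard metric?

`hrvconcord` answers it as a method-agreement analysis over a long
recording:

1. label every BBI clean / outlier / ectopic (`build_mask()`);
2. scan for 5-minute windows containing no labelled artifact
   (`scan_clean_segments()`);
3. greedily keep at most one window per hour (`select_hourly()`);
4. compute RMSSD, SDNN, LF and HF on each kept window and on its first
   minute (`compute_metrics()`, `extract_first_minute()`);
5. pool the pairs and report one Pearson correlation per metric with a
   categorical reading — excellent (r ≥ 0.9), good (0.7–0.9), moderate
   (0.4–0.7), low (< 0.4) (`run_concordance_study()`).

A deliberate design point inherited from the artifact-free-selection
tradition: artifacts are *labelled, never deleted*. Removing beats and
splicing would itself change RMSSD and the spectrum, confounding exactly the
comparison being made; selecting fully clean windows sidesteps that.

## Data model and conventions

Time is in milliseconds everywhere, on an absolute axis starting at 0 for
interval-only input. `bbi[i]` spans `(t[i], t[i+1]]`; a BBI belongs to a
half-open analysis window `[start, end)` only when both its endpoint beats
do, which makes "artifact-free window" unambiguous even when a BBI straddles
an edge. When a text file carries both beat times and stated intervals and
they disagree, the time column wins (it is the axis every downstream step
uses) and the reader warns; the stated interval on a line is interpreted as
the BBI *ending* at that line's beat time.

## Artifact rules

* **Outliers**: BBIs outside 400–1500 ms, the range corresponding to heart
  rates above 150 or below 40 BPM. Read strictly: the bounds themselves are
  clean (`bbi_to_heart_rate(400)` is exactly 150). Configurable via
  `outlier_rule()`.
* **Ectopic beats**: no universally fixed rule exists for interval-only
  data, so the package uses the de facto default of the screening packages
  in this space — a Malik-style relative criterion: a BBI deviating more
  than 20% from the most recent *accepted* (non-ectopic, non-outlier) BBI is
  ectopic; the first in-range BBI seeds the reference. Threshold and rule
  are explicit in `ectopic_rule()`, and outlier classification takes
  precedence when both fire.

One subtlety the test suite documents: "tightening the threshold never
shrinks the ectopic set" holds on physiological series, where flagged events
are isolated, but is *not* a theorem for the recursive rule — adversarial
three-beat sequences exist where the reference shift flips a later
classification. The property is therefore asserted on generator output, not
universally.

## Segmentation rules

Candidate 5-minute windows are evaluated on a 60-second start grid
(configurable `step_ms`): finer than the hourly selection it feeds, coarse
enough to bound compute on multi-day recordings. A qualifying window must
contain only clean BBIs and at least `min_beats` of them (default
`0.4 * duration_s` = 120 per 5 minutes — a guard against malformed masks;
truly clean windows always hold at least one beat per 1.5 s). Hourly
selection is greedy with inclusive start-to-start spacing: the first
candidate is kept, then the earliest candidate starting at least 60 minutes
after the last kept start. "At least 60 minutes later" is interpreted
start-to-start, the simplest consistent reading. The first minute of a kept
window is the sub-window `[start, start + 60 s)`; cleanliness is inherited.

## Metric computation

RMSSD and SDNN are the textbook formulas (`sqrt(mean(diff(x)^2))`; sample SD
with the n−1 divisor — the divisor is a documented choice, immaterial at
n ≈ 70–350). Both are checked against brute-force recomputation to 1e−9
relative on random inputs, and against the IID Gaussian closed forms
(SDNN → σ, RMSSD/SDNN → √2).

Frequency-domain metrics integrate an estimate of the tachogram power
spectral density over 0.04–0.15 Hz (LF) and 0.15–0.40 Hz (HF), in absolute
ms². Only the bands are canonical; the estimator is a package choice,
defaulting to the convention of the established HRV toolchains:

* cubic-spline interpolation of (beat time, BBI) onto a uniform 4 Hz grid,
  each BBI anchored at the beat that ends it;
* Welch's method: periodic Hann window, 256-sample segments (capped at the
  series length — a 60 s window yields a single 240-sample segment), 50%
  overlap, per-segment mean removal; one-sided density normalised so the
  integral recovers variance;
* trapezoidal integration over each band with interpolated band edges.

Numerical details that matter: outside the convex hull of the beat anchors
(up to one beat at each window edge) the spline is extended as a constant —
cubic extrapolation over even a fraction of a beat can ring by hundreds of
ms and measurably contaminate 1-minute band power. A classical Lomb–Scargle
periodogram (`estimator = "lomb_scargle"`) operating on the uneven points
directly, rescaled so its integral over the evaluated grid (up to the
mean-rate Nyquist, 4× oversampled) equals the sample variance, serves as a
robustness cross-check; the two estimators agree within a documented 25% on
stationary in-band signals and within ~1% on pure tones.

A 1-minute window covers only `lf_period_coverage(60) = 2.4` periods of the
0.04 Hz LF band edge. LF at 60 s is therefore computed *and* flagged: the
value is reported (mirroring ultra-short-term practice) with a resolution
warning whenever a window covers fewer than 5 lower-edge periods, silenced
inside the pipeline where the 60 s windows are intentional.

Windows with fewer than 4 BBIs get `NA` frequency metrics — never zeros —
and the CSV writer emits empty cells for them.

## The synthetic benchmark: what it emulates and what it does not

Clinical patch-ECG recordings are not redistributable, so validation runs on
`generate_recording()`: beats follow `t[k+1] = t[k] + m(t[k])` with

    m(t) = base + trend(t) + A_lf(t) sin(2π f_lf t + φ) +
           A_hf(t) sin(2π f_hf t + ψ) + ε,  ε ~ N(0, σ²)

evaluated at the previous beat — an adequate approximation of a fully
integrated pulse-modulation model while amplitudes are small against the
base interval. Defaults: base 850 ms; HF tone 0.25 Hz, 30 ms; LF tone
0.10 Hz, 45 ms; jitter σ = 10 ms; trend 250 ms over 2390 s; HF/LF amplitudes
wander sinusoidally by ±50% with 1700 s and 911 s periods. A validated
configuration bound (peak modulation < base) plus a runtime check guarantee
positive intervals.

Three design decisions here carry the whole benchmark:

* **Amplitude wander is essential.** With constant amplitudes every hourly
  segment has the same expected metrics and the pooled Pearson correlation
  degenerates into pure estimation noise.
* **All slow periods are incommensurate with the 3600 s segment spacing.**
  A wander period dividing one hour makes every hourly window sample the
  *identical* modulation phase — the between-segment variance silently
  collapses (with a 900 s wander the true HF amplitude is literally constant
  across hourly samples). Hence 1700 s, 911 s and 2390 s.
* **The wander hierarchy encodes the expected physiology.** The HF
  amplitude wanders slowly, so a 5-minute window and its first minute see
  nearly the same respiratory amplitude → HF (and RMSSD, which HF
  dominates) track tightly. The LF amplitude wanders on a sub-window scale
  and the 1-minute LF estimate rests on 2.4–6 tone periods → moderate
  tracking. The slow trend contributes variance ∝ (slope × window)² that a
  1-minute window sees at 1/25 of the 5-minute value → SDNN tracks worst.
  The acceptance suite asserts exactly this ordering (RMSSD ≈ HF > LF >
  SDNN, RMSSD and HF medians ≥ 0.8) over ten replicate 102-hour recordings
  — asserted as an ordering, not as specific correlation values, since the
  original clinical data is unavailable for numerical replication.

Injected artifacts preserve realism where it matters: an ectopic event is a
premature beat (0.6× the local BBI) plus compensatory pause (the removed
0.4× added to the next BBI), preserving cumulative time so segment grids are
unaffected; outliers are draws from outside 400–1500 ms and do shift later
beats. A single seed fans out to substreams (phases, jitter, injections), so
enabling injections does not perturb the underlying rhythm.

What the generator does **not** emulate: respiratory coupling to a breathing
model, heart-rate-dependent band boundaries, realistic artifact clustering
(motion bursts), missing data, or 1/f broadband variability. Passing the
benchmark therefore shows the *pipeline* is sound and that the qualitative
short-window mechanism is reproduced — it does not certify the numerical
correlations one would obtain on clinical recordings.

Two quantitative quirks of the beat-anchored recursion are worth knowing.
First, beats oversample fast phases, so over a long recording the mean BBI
converges to the harmonic-mean prediction `base − Var(m)/base` (≈ 811 ms at
defaults), not to `base`; the tests assert this corrected closed form.
Second, the generator writes the interval as a function of the *previous*
beat time while the tachogram anchors each BBI at its *ending* beat; this
one-beat phase lag is irrelevant to band power, and oracle tests that need
exact closed-form tachograms construct beats by fixed-point iteration
instead.

## Problem sizes and runtime choices

The shipped test and acceptance workloads are sized for a single CPU: the
concordance benchmark uses ten seeds × 102-hour recordings (~102 hourly
pairs per seed, ~430,000 beats each, ≈ 15 s per seed end to end); oracle
suites use 1000 random sequences (time domain) and single 5-minute windows
(spectral). `scripts/acceptance.R` recomputes everything from scratch in a
few minutes; all randomness derives from its `--seed` argument.

## Known limitations

* The ectopic rule is the inferred default of the field's toolchain, not a
  published per-study algorithm; results on artifact-dense data depend on
  it, which is why it is explicit and configurable.
* The Lomb–Scargle path normalises total grid power to the sample variance;
  with strong broadband noise above the evaluated grid this slightly
  inflates in-band density relative to Welch (the documented 25% agreement
  band, not a bias on tones).
* Pearson correlation is the agreement measure by design; it captures
  linear association, not bias or scale — Bland–Altman limits or intraclass
  correlation would be natural extensions.
* `select_hourly()` measures spacing start-to-start; alternative readings
  (end-to-start, calendar-hour binning) would shift segment counts by at
  most boundary effects.
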