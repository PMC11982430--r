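---
title: "Quantifying equine headshaking from poll-mounted accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying equine headshaking from poll-mounted accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headshakeR)
```

## The measurement problem

Trigeminal-mediated headshaking (TGMHS) is a neuropathic facial-pain
syndrome of the horse. Affected animals produce violent, predominantly
vertical head flicks whose intermittency makes severity grading by
observation subjective. A poll-mounted tri-axial accelerometer (±16 g,
800 Hz) worn during a standardised 5-minute trot on the lunge turns the
behaviour into a signal-processing problem: headshakes appear on the
vertical (Z) axis as brief, high-g biphasic transients superimposed on the
regular trot oscillation, while forelimb lameness appears as a
stride-locked asymmetric head nod of ordinary amplitude.

This package implements the full measurement chain: gravity correction,
supra-threshold peak detection, a per-recording feature set, nonparametric
cohort statistics, per-feature ROC evaluation with constrained threshold
selection, and a calibrated synthetic-cohort generator used for testing.

## Peak detection

The vertical axis is first gravity-corrected. The default subtracts the
per-recording **median** of Z rather than the nominal 1 g: for a level,
mostly-quiescent sensor the two coincide, but the median also absorbs
mounting tilt, which biases the static component on a headpiece-mounted
logger. The subtracted offset is stored on the signal for audit, and the
nominal method is available (`gravity_correct(rec, "nominal")`). Applying
the median correction twice removes a second offset of zero to numerical
precision, which the test suite checks.

Detection then scans for **maximal runs of consecutive samples strictly
beyond +1 g or below −1 g** that last at least **10 samples** (12.5 ms at
800 Hz). Each qualifying run becomes one peak whose amplitude is the signed
extremum within the run. Choices worth making explicit:

* *Width semantics.* "Minimum peak width" is interpreted as the full width
  of the contiguous supra-threshold run — the simplest semantics consistent
  with a width-in-samples parameter. It is encoded behind `peak_params()`
  so alternatives remain pluggable.
* *Strict inequalities.* A sample exactly at ±1 g does not count as beyond
  the threshold; this keeps the edge case of a ±1 g sinusoid unambiguous
  (zero peaks). The same strictness is used for the ±2 g feature counts and
  for threshold rules.
* *Plateaus* resolve to the first sample attaining the extremum.
* *One peak per excursion*, and positive and negative excursions are
  detected independently, so one biphasic shake yields one positive and one
  negative peak. No smoothing or filtering is applied before detection.
* *Rate rescaling.* At sampling rates other than 800 Hz the width minimum
  is rescaled to preserve its physical duration
  (`round(0.0125 s × rate)`).

The detector is verified against an independently written brute-force
scan oracle on a thousand random signals.

## Why 800 Hz matters

`resample_signal()` decimates through an FIR anti-aliasing low-pass
(via the signal package) and exists to demonstrate the degradation that
motivates recording at the native rate: a 12.5 ms half-sine transient — the
narrowest excursion the detector accepts — loses apparent height when
decimated to 200 Hz, because much of its spectral content lies near the
new Nyquist band. Two caveats the tests encode: the degradation direction
is only guaranteed for such narrow transients (wider flat-topped pulses can
*gain* a few percent from filter overshoot), and upsampling is refused
outright.

## The feature set

For one recording, `compute_features()` reports counts of positive peaks
(>+1 g) and negative peaks (<−1 g), their total and ratio, counts and
percentages beyond ±2 g, mean and extreme amplitudes per sign, and
per-minute rates over the actual recording duration (default 5 min).
Conventions:

* **Percentage denominator.** All percentages are fractions of *all*
  detected peaks (positive plus negative). Under this convention the
  combined percentage beyond 2 g is exactly the sum of the positive and
  negative percentages, which matches how the published group tables add
  up; the alternative (per-sign denominators) does not.
* **Undefined ratios.** With zero negative peaks the positive:negative
  ratio is reported as `NA`, not infinity: nonparametric statistics drop
  missing rows pairwise, whereas an infinity would poison rank sums.
  Likewise means and extrema of an empty sign are `NA`, while percentages
  of an empty peak set are 0.

## Cohort statistics

Group comparisons are nonparametric throughout, reflecting the skewed,
small-sample nature of the data. Two-group contrasts (TGMHS versus all
other horses) use two-sided Mann–Whitney tests; the U statistic is computed
in-package from midranks and the p-value is delegated to
`stats::wilcox.test` (exact when the sample-size product is at most 400 and
there are no ties, tie-corrected normal approximation with continuity
correction otherwise). Four-group omnibus tests use tie-corrected
Kruskal–Wallis via `stats::kruskal.test`, with pairwise post hoc
Mann–Whitney tests run only when the omnibus is significant. Multiplicity
is controlled by **Bonferroni** division of the familywise 0.05 — the
standard conservative default for a small family of planned comparisons —
over the post hoc pairs, or over the feature set for the two-group series.

ROC evaluation is per feature. The empirical AUC is the normalised
Mann–Whitney U of the cases (`AUC = U/(n₁n₂)`), reported under the fixed
orientation "higher value indicates a case"; negative-g amplitude features
therefore show AUC below 0.5, and `effective_auc = max(AUC, 1−AUC)` gives
the orientation-free discrimination. AUC bands follow the conventional
cut-points (0.7–0.8 acceptable, 0.8–0.9 excellent, >0.9 outstanding).
Confidence intervals use DeLong's method (via pROC) by default; a seeded
stratified percentile bootstrap (2000 replicates) is available as a
cross-check, and a test confirms the two approach each other at large
replicate counts.

Threshold selection mirrors the study's rule: candidate cut-offs lie at
midpoints between adjacent distinct observed values; among operating points
with **sensitivity and specificity both ≥ 0.80** the one maximising
Youden's J is returned, and if no point qualifies the global Youden optimum
is returned flagged `constraint_met = FALSE` rather than silently relaxing
the constraint. Reported sensitivity and specificity are exact confusion
fractions of the input at the returned cut-off, which a test re-derives by
direct counting. Predictive values use the closed Bayes forms at a supplied
prevalence; they are undefined at prevalence 0 or 1 and error rather than
returning a vacuous number.

## Packaged threshold rules

`default_rules()` ships the published per-feature rules (AUC, CI, cut-off,
sensitivity, specificity) verbatim from a constants table, guarded by a
byte-for-byte test against the TSV under `inst/extdata/`. Two published
rules — the two single-sign percentage features — carry a printed cut-off
of −1.00, which cannot be meaningful for a percentage (every recording
would trigger them). Their intended values are unknown and are **not
guessed**: the rows are retained for completeness, flagged
`suspect = TRUE`, and excluded from default rule application. The two
negative-amplitude rules point downward (`direction = "below"`), consistent
with their published sub-0.5 AUCs under the fixed orientation.
`apply_rules()` reports a transparent fraction of rules met; no combined
diagnostic score is invented, because the features were validated
individually — the output is a set of TGMHS-consistent movement flags, not
a diagnosis.

## The synthetic cohort generator

No recordings are distributed with the study, so the generator is the
package's test bed. It emulates, per group:

* a trot-periodic baseline at `stride_rate` (default ≈1.6 Hz) whose
  positive and negative half-cycle amplitudes are drawn from separate
  lognormal distributions — separate, because the published groups cross
  the −1 g threshold far more often than the +1 g one;
* stride-locked alternating amplitude modulation (`asymmetry`, default
  0.15 for the lame group) emulating the lameness head nod;
* white sensor noise (`noise_sd`, default 0.05 g);
* biphasic headshake bursts — one dominant positive then one negative
  half-sine lobe over `shake_width_s` (default 0.25 s) — at Poisson times
  with a minimum 0.3 s inter-event gap so that injected events stay
  disjoint and can be matched against detections;
* a +1 g gravity offset, low-amplitude noise on the horizontal axes, and
  clipping at the ±16 g device range.

Per-horse variability is introduced by jittering each group profile
(seeded) before simulation, and features are always computed **through the
real pipeline** — correction, detection, feature computation — never
shortcut. `calibrate_profiles()` tunes profile locations by deterministic
seeded coordinate descent against the packaged published group medians;
because exact distributional recovery from medians and IQRs is
underdetermined, calibration targets agreement within roughly 25–40% per
feature median and reports the achieved deviations rather than claiming an
exact match. The shipped `default_profiles()` are the frozen product of
that calibration plus manual refinement, with burst rates around 10/min
for TGMHS, 3/min (negative-dominant) for non-TGMHS, and none for lame and
control profiles.

What the generator does **not** emulate: biomechanically realistic gait,
rider or handler effects, surface and environmental triggers, drift or
temperature effects in the sensor, and any horizontal-axis structure. A
green synthetic test therefore shows that the pipeline recovers what was
injected under the stated signal model, not that the model exhausts real
equine data.

## Numerical choices and degenerate inputs

* Signals shorter than the width minimum yield an empty peak table with a
  warning, not an error.
* Saturated samples are clipped to the device range with a warning,
  mirroring the real sensor, and the clip count is kept on the recording.
* A feature constant across both classes yields AUC 0.5 with a warning;
  placing a threshold on it is an error.
* Exact Mann–Whitney with ties falls back to the approximation with a
  warning.
* Recording files are written with `%.17g` precision so read/write round
  trips are bit-exact.
* All simulation entry points take explicit integer seeds; the same seed
  reproduces a cohort bit-for-bit.

## Problem sizes used by the tests

The suite verifies the detector against its oracle on 1000 random signals
of up to 1000 samples; Mann–Whitney against full enumeration for all
sample-size pairs up to 8×8; the AUC/U identity and orientation
antisymmetry on 100 random datasets; burst recovery (≥95% of injected
≥3 g events matched within ±50 ms) over 50 seeded 1-minute recordings; and
the headline discrimination on 20 seeded replicates of the full 56-horse,
5-minute cohort. These sizes were chosen so the whole suite runs in a few
minutes on one CPU while keeping the stochastic checks well-powered.

## Known limitations

Only the vertical axis is analysed, as in the validation study; the
horizontal axes are carried but untouched. The proprietary binary format
of the logger is out of scope — recordings must be exported to delimited
text first. The packaged rules inherit the published values, including the
two uninterpretable percentage cut-offs noted above, and the published
prevalence (18/56) is that of a referral population, so predictive values
computed at it do not transfer to field screening populations.
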