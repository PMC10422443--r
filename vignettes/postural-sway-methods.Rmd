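---
title: "Postural sway from a chest-worn accelerometer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postural sway from a chest-worn accelerometer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaysense)
```

## The measurement model

A small adhesive sensor on the sternum records 3-axis acceleration in G at
a nominal 50 Hz with a ±8 G full scale. During quasi-static balance tasks
the dominant component of the measured vector is gravity, so the vector's
direction encodes the device's inclination, and the residual fluctuation
around it encodes postural sway. `swaysense` works entirely from that
single modality: no gyroscope or magnetometer fusion is attempted, because
the commercial device's fusion algorithm is proprietary and a
gravity-referenced tilt is sufficient for sway quantification.

### Tilt

For a sample $(a_x, a_y, a_z)$ the independent per-axis inclinations are

$$\theta = \tan^{-1}\!\frac{a_x}{\sqrt{a_y^2+a_z^2}},\qquad
  \psi   = \tan^{-1}\!\frac{a_y}{\sqrt{a_x^2+a_z^2}},\qquad
  \varphi = \tan^{-1}\!\frac{\sqrt{a_x^2+a_y^2}}{a_z},$$

in degrees. Two companion forms are exposed for completeness: the planar
arctangent $\tan^{-1}(a_x/a_y)$ and the gravity-vector arccosine
$\cos^{-1}(a_z/\lVert a\rVert)$, which coincides with $\varphi$ on the
upper hemisphere (an identity the test suite asserts to $10^{-9}$
degrees). The planar form divides by a single axis rather than the norm of
the remaining plane; it is implemented exactly as stated for parity but
the pipeline uses the independent-inclination form throughout, whose
denominators degrade gracefully.

These formulas fold every orientation into the upper hemisphere, so a
quadrant-resolution step restores the full 360° range from the signs of
the components: the plane-projection denominator of $\theta$ and $\psi$
carries the sign of $a_z$ (two-argument arctangent semantics), reflecting
the angles through $\pm(180° - |\cdot|)$ when the device tilts past
horizontal, and $\varphi = \mathrm{atan2}(\sqrt{a_x^2+a_y^2}, a_z) \in
[0°, 180°]$ is already full-range. The step is idempotent and is applied
after decimation, per retained sample.

Numerical edge cases are handled deliberately: zero denominators return
the signed 90° limit (the two-argument arctangent is exact there), so
behaviour is continuous at gimbal boundaries, while an exactly zero
acceleration vector raises an `undefined-orientation` error — in free
fall there is no gravity reference and no meaningful tilt.

Tilt is computed at 25 Hz by keeping every second sample of the 50 Hz
stream. No anti-alias filter precedes the decimation: the scored sway
band (0.1–2 Hz) sits far below the 12.5 Hz post-decimation Nyquist, and
no filtering is part of the described processing chain.

### Sway features

Per device axis, the amplitude series AMP is the within-window
max − min over complete, non-overlapping one-second windows aligned to
trial start; the RMS series is the root mean square of consecutive,
non-overlapping groups of three AMP values, i.e. one value per 3 s. A
$T$-second trial therefore yields $\lfloor T\rfloor$ AMP and $\lfloor
T/3\rfloor$ RMS values per axis, and trials shorter than 3 s are rejected.
Two properties follow directly and are exercised as invariants: max − min
is translation-invariant, so the constant gravity offset cancels without
any explicit detrending, and the features scale exactly linearly with the
dynamic part of the signal.

The windowed cadence ("updated every second", "groups of three") could be
read as overlapping; non-overlapping windows were chosen because no
overlap is described and the 3 s update interval then falls out exactly.

### Scores, axes, and what "sway score" means

The published group tables report a single "posture sway" scalar per
subject and direction without defining it. The package defines the axis
score as the mean of that axis's RMS series over the trial, in G — the
simplest statistic consistent with a 3 s RMS update — and the mean score
as the arithmetic mean over the three anatomical directions, matching the
"mean of three directions" convention. Acceleration RMS (not tilt RMS)
is scored: the published group means of 0.16–0.47 are dimensionally
plausible as G-valued acceleration amplitudes, not as degree-valued tilt
amplitudes. The per-second tilt amplitude is still computed and reported
alongside, but never scored.

Device axes map to anatomical directions anterior–posterior (AP),
medial–lateral (ML) and vertical (V). For a patch worn flat on the chest
the default is Z→AP (outward), X→ML, Y→V; the placement figure does not
state the mapping, so it is configurable and validated as a bijection.

## Diagnostic evaluation

Fallers are labelled either by clinical criteria — BBS below 40
(strictly; an inclusive "40 or less" mode exists because the clinical
description of the scale uses that phrasing) or TUG above 14 s — or by
3-month fall history. Higher sway predicts faller status; the decision
rule is fixed in that direction because the MCI group's sway means are the
larger ones.

The ROC curve sweeps thresholds over every unique observed score plus an
infinite sentinel under score ≥ threshold ⇒ positive. The AUC is the
trapezoidal area, which for this construction equals the Mann–Whitney
probability that a random positive outscores a random negative with ties
counted one half — an equivalence the tests verify exhaustively on all
small cohorts. The standard error uses the Hanley–McNeil nonparametric
formula with a normal 95% interval clipped to [0, 1]; the source tables
do not state their interval method, and this choice reproduces their
0.99-capped upper bounds. (Their printed SE column, 0.40–0.73, is
inconsistent with their own CI widths by an order of magnitude and is not
treated as a target.) The Youden cut-off maximises
$J = \text{sens} + \text{spec} - 1$, breaking ties towards higher
sensitivity and then towards the lower threshold, so screening
applications keep the more sensitive operating point.

Sensitivity, specificity and accuracy use the standard confusion-matrix
forms, with specificity = TN/(TN+FP); zero denominators yield an `NA`
marker rather than an error, since a one-class margin is a data property,
not a programming fault. Grades band the proportions as ≥ 0.81 excellent,
0.61–0.80 good, 0.41–0.60 moderate, below 0.41 poor; the published bands
leave the gaps 0.80–0.81 and 0.60–0.61 and say nothing below 0.41, and
the bands here close those gaps to cover [0, 1] contiguously.

Group contrasts are Welch's unequal-variance t-test computed from summary
statistics (mean, SD, n per group); pooling was rejected because the two
study groups have visibly unequal variances (e.g. BBS SD 1.33 vs 5.88).

## The synthetic cohort

With no public study data, the generator emulates the study conditions at
two levels.

**Score level.** Per-group sway scores are plain Gaussian draws at the
published moments — BBS-context 0.16 ± 0.20 G (healthy) vs 0.41 ± 0.12 G
(MCI); TUG-context 0.36 ± 0.08 vs 0.47 ± 0.12 — with 20 subjects per
group by default. Negative draws are permitted: only mean and SD are
published, and truncating would bias exactly the moments being matched.
Clinical scores are Gaussian at the published moments with BBS rounded
and clipped to [0, 56] and TUG clipped positive. Fall history mirrors
the study's inclusion criteria (every MCI participant had a recent fall,
no healthy participant did). Under these moments the closed-form binormal
AUC $\Phi(\Delta\mu/\sqrt{\sigma_0^2+\sigma_1^2})$ is 0.858 (BBS context)
and 0.777 (TUG context) — inside the published 95% intervals [0.84, 0.99]
and [0.70, 0.97] but below the published point estimates of 0.92 and
0.84, which derive from 40 real participants whose score distributions
are unknown. The simulation therefore reproduces interval-level, not
point-level, agreement, and that is the designed expectation.

**Signal level.** A trial is gravity baseline + sway + noise per axis,
with the sway a sum of three random-phase sinusoids with frequencies
uniform in 0.1–2 Hz — the typical postural-sway bandwidth and the
simplest controllable model — scaled to a per-axis peak amplitude in G,
plus white Gaussian noise (default SD 0.005 G, a realistic accelerometer
noise floor; zero in calibration-sensitive tests for exactness). Signal
defaults use 12 s trials: four complete RMS windows, enough for a stable
score at test-suite cost. A monotone bisection calibrates the amplitude
so the pipeline's mean score hits a target within 2%; since score-level
targets can be negative, signal targets are clamped at zero first — a
monotone transform that leaves the cohort's AUC essentially unchanged
(MCI mass below zero is negligible). One global seed fans out to
per-subject substreams so a subject's trial is reproducible regardless of
cohort size. What the generator does **not** emulate: task phases of the
clinical tests (chair rise, turning), impact events, sensor bias drift,
or any non-Gaussian features of real score distributions — so passing
tests demonstrate pipeline correctness and statistical consistency, not
clinical performance on real patients.

## Problem sizes and verification

The test suite checks the windowing arithmetic and tilt identities
exactly (to $10^{-9}$), the ROC stack against exhaustive pair counting
and exhaustive Youden search on random cohorts of up to 12 subjects, the
gravity/inclination identity on $10^5$ random unit vectors, and the
package's Welch test against `stats::t.test` and its type-I error at
1000 null replicates (0.05 ± 0.015). Cohort-level checks draw 20,000
subjects per group at the published moments — large enough that the
Monte-Carlo SE of the empirical AUC is below 0.003 — and a full
signal-level cohort of 20 + 20 subjects is pushed through calibration,
generation and scoring to confirm it reproduces the score-level AUC
within three Monte-Carlo standard errors. `scripts/acceptance.R` re-runs
the cohort-level computation from scratch against the installed package.

## Known limitations

- The sway-score definition (mean 3 s RMS) is a reconstruction; other
  statistics over the RMS series would change absolute score values,
  though not the qualitative group separation.
- Score-level cohorts attach one drawn score to all three directions, so
  per-direction results coincide there; per-direction variation requires
  signal-level simulation with per-axis amplitudes.
- The Hanley–McNeil interval is asymptotic-normal and can be conservative
  near AUC = 1 at n = 20 per group.
- Accuracy at the Youden cut-off depends on the cohort's class balance;
  published accuracy values whose denominator population is unclear are
  not comparable targets.
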