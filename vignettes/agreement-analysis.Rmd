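---
title: "Agreement analysis for paired joint-angle waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis for paired joint-angle waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinagree)
library(dplyr)
```

## The problem

Markerless (video-based) motion capture is rapidly replacing marker-based
systems for field testing of team-sport athletes, but its joint-angle
estimates cannot be assumed interchangeable with the marker-based reference
standard. `kinagree` quantifies the agreement between the two technologies
for lower-limb joint angles during change-of-direction running, where both
systems are challenged by rapid decelerations: a protocol of straight
running plus 45/90/135/180-degree cuts, each at three intensities with three
repetitions, recorded simultaneously by both systems.

Agreement is summarized two ways, matching how the field reports it:

* **discrete events** — joint angles at touchdown, toe-off, and the stance
  peaks — analyzed with an extended Bland–Altman model for repeated
  measures, giving a bias line and limits of agreement (LoA);
* **whole difference waveforms** over the stance phase, summarized by
  bootstrapped functional prediction bands and the area between the band
  edges (deg·stance%).

## The extended Bland–Altman model

For one stratum, angle, and event, let \(d_{ij}\) be the difference
(test − reference) for trial \(j\) of participant \(i\), and \(x_{ij}\) the
reference value. The package fits the linear mixed-effects model

\[
d_{ij} = \beta_0 + \beta_1\,(x_{ij} - \bar x) + u_i + e_{ij},
\qquad u_i \sim N(0, \sigma_b^2),\quad e_{ij} \sim N(0, \sigma_w^2).
\]

The fixed-effect line is the *bias line*; because the covariate is centered,
\(\beta_0\) is the bias at the mean reference value, which is how every bias
in the package is reported. Putting the reference value (rather than the
average of the two methods) on the abscissa is a deliberate deviation from
the classical Bland–Altman convention: the marker-based system is treated
as the reference standard, and the slope \(\beta_1\) then reads directly as
the change in between-system difference per degree of reference angle.

The participant random intercept absorbs the repeated-measures dependence.
The *adjusted SD* of a single new difference combines both variance
components, and the limits of agreement are

\[
\mathrm{LoA} = \beta_0 \pm 1.96\,\sqrt{\sigma_b^2 + \sigma_w^2}.
\]

This equates the mixed-model variance decomposition with the classical
one-way-ANOVA decomposition for repeated measures: the mean squares satisfy
\(\mathrm{MSW} = \hat\sigma_w^2\) and
\(\mathrm{MSB} = \hat\sigma_w^2 + m\hat\sigma_b^2\) with \(m = N/n\)
observations per participant, so the two routes estimate the same total
variance. With exactly one observation per participant the model degenerates
to the classical analysis (mean difference ± 1.96 SD), which
`fit_extended_ba()` then computes through a fixed-effects fit; the test
suite checks this equivalence to 1e-6.

### Confidence intervals

Symmetric 95% intervals use the variance of the estimated quantities under
the same decomposition:

\[
\mathrm{var}(\hat\beta_0) = \frac{\sigma_b^2}{n} + \frac{\sigma_w^2}{N},
\qquad
\mathrm{var}(\hat s^2) =
\frac{2(\sigma_w^2 + m\sigma_b^2)^2}{m^2 (n-1)} +
\frac{2(1 - 1/m)^2 \sigma_w^4}{N - n},
\]

with \(\mathrm{var}(\hat s) = \mathrm{var}(\hat s^2)/(4 s^2)\) and
\(\mathrm{var}(\widehat{\mathrm{LoA}}) = \mathrm{var}(\hat\beta_0) +
1.96^2\,\mathrm{var}(\hat s)\). The two terms of \(\mathrm{var}(\hat s^2)\)
are the chi-square sampling variances of the between- and within-participant
mean squares. Normal (1.96) quantiles are used rather than t quantiles,
matching the multiplier of the limits themselves; with the study-scale 19
participants the difference is small, and a t refinement would need a
degrees-of-freedom convention for the variance of a variance component that
has no exact answer. Intervals are reported as missing below 3 participants.

A 200-replicate recovery simulation at the study scale (19 participants ×
45 trials, participant SD 2°, residual SD 3°) is part of the test suite:
the bias CI covers the injected bias in ≥ 90% of replicates and the
estimated LoA half-width is within 10% of \(1.96\sqrt{13}\).

### Assumption checks

Each fitted model is screened with the three rules used in practice, on the
conditional (level-1) residuals:

| check | statistic | violated when |
|---|---|---|
| normality | Shapiro–Wilk on residuals | p < 0.05 |
| linearity | Spearman rank correlation, residuals vs fitted | p < 0.05 **and** \(|\rho|\) > 0.3 |
| heteroscedasticity | regression of \(|\)residuals\(|\) on fitted | p < 0.05 **and** \(|\)slope\(|\) > 0.1 |

The dual conditions matter: at study sample sizes a p-value alone flags
trivially small effects. Constant residuals (a degenerate but legal input)
leave the normality test undefined and are reported as non-violating with a
note. Above 5000 residuals the Shapiro–Wilk test is applied to a
deterministic evenly spaced subsample, which keeps the pipeline defined for
pooled strata of arbitrary size.

## Functional prediction bands

For whole difference waveforms the package computes a band expected to
contain 95% of *new* curves from the same process. Each 101-point curve is
first smoothed with a truncated Fourier basis of 12 harmonics plus a linear
trend term; the trend term keeps non-periodic curves honest at the stance
endpoints, and 12 harmonics resolve structure down to ~8% of stance, ample
for low-pass-filtered kinematics. The band is

\[
\hat\mu(t) \pm c\,\hat\sigma(t)
\]

with \(\hat\mu, \hat\sigma\) the pointwise mean and SD of the smoothed
curves. The multiplier \(c\) is calibrated by bootstrap (400 iterations, the
convention for this band family): each iteration resamples the curves —
whole participants with all their trials when trials are dependent, the
default — recomputes the resample's mean and SD functions, and records the
maximum over stance of \(|y(t) - \hat\mu_b(t)|/\hat\sigma_b(t)\) for one
picked curve. \(c\) is the upper 95% empirical quantile of these maxima
(the smallest multiplier attaining the 95% fraction, ties resolved upward).

Two details of this scheme were genuinely open and were settled by coverage
calibration on synthetic Gaussian-process ensembles:

* **Pick rule.** Evaluating containment of the original curves against the
  final band systematically undercovers fresh curves (mean coverage ~0.89
  at n = 50 in our calibration runs): the curves being contained also built
  the band. Picking only out-of-bag curves overcovers (~0.96–0.97).
  Alternating in-bag and out-of-bag picks by iteration parity centers
  fresh-curve coverage at the nominal level (mean ~0.95–0.96, SD ~0.03 at
  n = 50); that residual spread is the sampling noise of a band estimated
  from 50 curves, not removable by more bootstrap iterations.
* **Multiplier search.** The upper order statistic
  \(M_{(\lceil(1-\alpha)B\rceil)}\) is used directly instead of an iterative
  search; it is exactly the smallest multiplier achieving the target
  fraction on the bootstrap reference distribution.

Band summaries follow the reporting conventions: the area between the edges
(trapezoidal integral over the 0–100% stance grid, deg·stance%), the
maximum and minimum width, and the mean of the mean-difference curve.
Bands are shift- and scale-equivariant, and a stricter \(\alpha\) always
yields a containing band on the same resamples; both are property-tested.

## Preprocessing chain

* **Stance detection**: longest contiguous run of vertical force strictly
  above 20 N, both indices inclusive; ties resolved to the earliest run
  with a message. Trials with no usable stance are dropped and counted,
  never imputed.
* **Filtering**: 4th-order zero-phase Butterworth low-pass at 20 Hz on the
  reference system's angle and force channels. The zero-phase pass is
  implemented with odd-reflection padding *and* steady-state initial filter
  conditions; without the initial conditions a constant signal picks up
  multi-degree edge transients, which is why the package does not call a
  stock two-pass routine. Test-system curves are not filtered — their
  smoothing happens upstream in the pose-estimation software.
* **Resampling**: the reference (200 Hz) is interpolated onto the
  test-system rate (85 Hz) after filtering (the low-pass already prevents
  aliasing); cubic by default. The output grid spans exactly the input
  interval; its size is the number of complete output intervals fitting the
  span, evaluated with a small tolerance so that rates re-derived from
  stored time stamps cannot flip a boundary case.
* **Time normalization**: the stance segment of every curve is interpolated
  (linear by default, cubic optional) onto 101 equally spaced points —
  stance 0–100% in unit steps, endpoints preserved exactly.
* **Events**: touchdown and toe-off are the first and last normalized
  values; the peak minimum/maximum are global extrema over all 101 points,
  not local peaks — "peak angle during stance" is read as a stance-wide
  extremum.
* **Approach speed**: mean frame-to-frame horizontal speed over the 0.2 s
  window ending at touchdown.

Whether filtering should precede or follow downsampling is not dictated by
anything in the data; the package filters at the native rate first, which
uses the full bandwidth for the filter and makes the later interpolation
benign.

## The synthetic-data generator

No public recording of this protocol exists, so validation rests on a
generator whose defaults *are* the emulated study conditions: 19
participants × 5 directions × 3 intensities × 3 repetitions (45 trials per
participant), 9 angle series per trial, reference at 200 Hz with a force
channel, test at 85 Hz. Choices a user should know:

* **Curve morphology** is a low-order harmonic mixture (4 harmonics with
  decaying, jittered weights) over a stance duration drawn per direction
  (0.20–0.26 s for straight running up to 0.34–0.45 s for the 180° cut),
  with amplitudes largest in the sagittal plane. Only the statistics of the
  curves matter downstream; no biomechanical forward model is attempted.
* **The difference structure is the estimand.** The generator plants a fixed
  bias, a proportional-bias slope, participant random intercepts, and a
  smooth residual process (squared-exponential correlation, default length
  10% of the curve), optionally heteroscedastic and optionally skew-normal
  or heavy-tailed (multivariate-t, 4 df) to exercise the normality-violation
  path. Defaults (bias 4°, slope −0.3, participant SD 2.5°, residual SD 5°)
  sit at the magnitudes this kind of system comparison reports, giving LoA
  near ±11°. With every parameter zero the two systems agree exactly — the
  end-to-end identity test.
* **Approach speeds** are drawn per direction from ranges whose means
  decrease with cutting sharpness, partitioned by instructed intensity, so
  that direction-specific speed tertiles recover the intensity structure.
* **Seeding**: one global seed; each trial derives its own substream from a
  counter, so any subset of trials is reproducible independently of
  generation order.

What the generator does **not** emulate: soft-tissue artifact, marker
occlusion and pose-estimation failure modes, cross-talk between angle
components, or any systematic error that depends on movement phase in a way
the linear difference structure cannot express. Passing recovery tests
therefore validates the *estimators*, not the field behavior of any
particular capture system.

## The three-level pipeline

`run_study()` fits one extended Bland–Altman model per stratum × angle ×
event and one band per stratum × angle, at three stratification levels:
pooled, per direction, and per direction × intensity — 21 strata and, with
9 angles and 4 events, 756 model specifications under the default design.
Intensity in the strata means *measured* speed tertiles (at-or-below /
strictly-above the empirical 1/3 and 2/3 quantiles, per direction by
default), not the instructed labels. Pooling at level 1 is per trial, not
per participant. Aggregation reports means of absolute bias (alongside
signed means), LoA, slope, and band area per joint, plane, direction and
intensity; specifications with fewer than `min_observations` events or 2
participants are skipped and counted, so enumerated = fitted + skipped
always holds.

## Problem sizes used in the tests

The test suite validates estimator behavior at the smallest sizes where the
properties are meaningful: recovery simulations run 200 replicates at the
full event-level study scale (19 × 45); waveform-level end-to-end tests use
2–6 participants with 1–2 angle series; band coverage uses the 50-curve /
1000-fresh-curve design with the full 400 bootstrap iterations. These sizes
are the package's own choice of the smallest faithful test problems.

## Known limitations

* The LoA is a single adjusted-SD interval per model even when the bias
  slope is large; no magnitude-dependent (regression-based) LoA is offered.
* CI quantiles are normal, not t; below ~10 participants the intervals are
  mildly anticonservative.
* The band multiplier is one scalar: the band cannot be locally wider where
  the SD function is poorly estimated.
* Non-convergent mixed models are refit once with a different optimizer,
  then flagged and excluded from aggregate means (the exclusion is
  counted); they are not otherwise repaired.
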