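---
title: "Analyzing 24-hour movement behaviors against hippocampal gray matter:
  models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing 24-hour movement behaviors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movecomp)
```

## Overview

`movecomp` analyzes the relation between daily movement behaviors —
sleep, sedentary time (SED), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA) — and a continuous outcome,
hippocampal gray-matter volume (GMV, mm³), in cohorts of children with
overweight/obesity. Because the four behaviors exhaust the 1440-minute day,
they form a *composition*: raising one necessarily lowers the others, and
the minute variables are strongly collinear. The package therefore carries
three complementary model families side by side — standard regression on
absolute minutes, compositional regression on log-ratio coordinates, and a
PLS-based multivariate pattern analysis of the full intensity spectrum —
plus the accelerometer reduction that produces their inputs and a synthetic
cohort generator that emulates the study design the analyses assume.

## Accelerometer reduction

Input is an epoch-level series of ENMO acceleration magnitudes in
milli-gravitational units (m*g*) with wear and sleep annotations. Choices
that matter:

* **Thresholds.** SED < 35 m*g*, LPA 35–200 m*g*, MVPA > 200 m*g*
  (non-dominant-wrist, children). The sources write "<35", "35–200", ">200",
  leaving both boundary values to LPA; we adopt that closed–closed LPA
  convention and expose the cut-points as an argument.
* **Intensity spectrum.** Awake time only, binned into 33 bands of 25 m*g*.
  33 × 25 = 825 would orphan higher accelerations, so band 33 is open-ended
  (≥ 800 m*g*). Band edges are half-open `[lo, hi)`.
* **Non-wear imputation.** A non-wear epoch takes the mean magnitude at the
  same clock time over all other worn days. A slot that is non-wear on every
  day is flagged unimputable and excluded from summaries. Imputation fills
  values but does not create wear time: daily validity (≥ 16 h) counts
  measured wear only.
* **Weighting and validity.** Behavior minutes and spectrum bands are
  averaged within valid weekdays and valid weekend days separately and
  combined as (weekday × 5 + weekend × 2) / 7; the weighting is applied
  uniformly to classes and spectrum (the sources do not distinguish).
  Participants need ≥ 4 valid days including ≥ 1 weekend day.
* **Epoch length** is configurable (default 5 s) and must divide 60 s;
  raw-signal processing (100 Hz autocalibration, sleep detection, non-wear
  detection) is out of scope — wear and sleep flags are inputs.

## Standard models and the moderation screen

`fit_absolute()` is ordinary least squares of GMV on one behavior's daily
minutes plus the fixed covariate set used everywhere: sex,
peak-height-velocity (PHV) offset from the Moore equations (boys:
−8.13 + 0.007·(age × seated height); girls: −7.71 + 0.004·(age × height),
heights in cm, applied literally — the sources do not state a different unit
convention for girls), parental university education as two dummies against
"neither parent", and total brain volume. Each behavior is modelled in
isolation, which is exactly the interpretation problem the compositional
models fix, but it allows comparison with the older literature.

`test_moderation()` compares the covariate-adjusted model with and without
behavior × weight-status interaction terms by a joint F-test (2 df with all
three groups; the per-term alternative is not identified in the sources, so
the joint test was chosen). The screen uses a deliberately liberal
α = 0.15; a flag triggers `stratify_and_fit()` within the weight-status
groups (overweight, obesity I, obesity II–III). Property tests confirm the
screen holds its nominal type-I rate (0.15 ± 0.03 over 2000 null
simulations).

## Compositional analysis

`ilr_pivot()` maps a 4-part composition to three pivot coordinates,

$$z_k = \sqrt{\tfrac{D-k}{D-k+1}}\;
  \ln\!\frac{x_k}{\mathrm{gmean}(x_{k+1},\dots,x_D)},\qquad k = 1..D-1,$$

with the focal behavior rotated into first position, so $z_1$ contrasts it
against the geometric mean of the remaining behaviors. The normalization
constant follows the standard sequential-binary-partition construction; the
original appendix describing the exact basis was not available, so this
choice is documented rather than inherited. The transform is
scale-invariant and exactly invertible; model fit (predictions, R²) does not
depend on the rotation — only which coefficient is labelled γ changes, and
both facts are property-tested.

`fit_compositional()` regresses the outcome on all three coordinates plus
the covariates; γ is the coefficient of $z_1$ with its 95 % t-interval.
Zero parts are an error by default (the emulated cohorts have MVPA means
around 50 min/day, so true zeros indicate an upstream problem); a
1-minute multiplicative replacement can be applied manually before closure.

`substitution_curve()` predicts the outcome difference when δ min/day move
from a donor to a receiver behavior, starting from a base composition
(default: the stratum's compositional mean, i.e. the closed geometric mean).
Covariates cancel in the difference; because the difference is linear in the
fitted ilr coefficients, the confidence band comes from the delta method,
$\mathrm{var} = d^\top V d$ with $d$ the ilr difference vector (a bootstrap
is unnecessary for a linear functional of the coefficients). The curve is 0
at δ = 0 by construction and is defined only while the donor stays positive;
infeasible grid points are truncated with a warning. Whether covariates are
held at means or reference levels is immaterial for the difference curve.

## Multivariate pattern analysis

The 33 spectrum bands are completely collinear by construction, which is the
point: `pls_fit()` implements single-response PLS (NIPALS), tolerating
duplicate columns. Pre-treatment mean-centers and unit-variance scales the
bands (the standard pretreatment in the selectivity-ratio workflow; the
sources are silent, so it is an argument). Covariates are handled by
residualizing the outcome on them first — PLS has no native covariate slot
and the same confounder set is used everywhere; residualizing X as well is
possible but not the default.

Component count is selected by Monte-Carlo cross-validation: repeated
random 50/50 splits (default 1000 repetitions), mean squared prediction
error per candidate count including the 0-component (training-mean)
reference. The selected count is the smallest within one standard error of
the minimum; selecting 0 is reported as "no predictive model", mirroring how
most strata in this design genuinely show no validated association. If the
(residual) response is orthogonal to the predictors, extraction stops early
and a mean-only model is returned with a warning rather than an error.

`target_project()` compresses a k-component model into a single component
along the normalized regression vector; its predictions equal the full
model's exactly (checked to 1e-8). Per band, the selectivity ratio is the
signed share of the band's variance explained by that component,
$SR_j = \mathrm{sign}(p_{tp,j})\,\mathrm{var}(t_{tp} p_{tp,j}) /
\mathrm{var}(x_j) \in [-1, 1]$; zero-variance bands are reported missing.
The 95 % intervals are 2.5/97.5 percentiles of the ratios recomputed on each
Monte-Carlo training split (the sources state "95 % confidence intervals"
without a method; the percentile choice reuses the CV machinery and is
seed-reproducible).

## The synthetic cohort: what it emulates and what it does not

No participant-level data were deposited, so the generator *is* the stated
world the tests run in:

* 93 children in groups of 23/41/29 (overweight, obesity I, obesity II–III),
  girls 9/15/13, ages ~8–12.
* Compositions are logistic-normal: per-group target means (group
  descriptive tables; e.g. obesity I SED 559.35, LPA 273.16, MVPA 53.84,
  sleep the 1440 remainder) times correlated log-normal perturbations with
  half-log-variance mean correction, re-closed to 1440. Log-scale SDs
  (0.064, 0.135, 0.155, 0.40) and a +0.5 LPA–MVPA log-correlation were
  calibrated once so minute-scale SDs approximate the published SDs and
  pairwise SED/LPA/MVPA correlations land in the published 0.3–0.5 band
  (closure makes SED–PA correlations negative). The sleep SD (35 min) is a
  field-typical value; the sources publish no sleep dispersion.
* The spectrum partitions each behavior's minutes across its m*g* range
  with a geometric decay (ratio 0.75; activity time concentrates at low
  accelerations) plus per-participant log-normal jitter (SD 0.3) so the
  matrix has full rank; no spectral shape is published, so both are
  arguments.
* Outcomes are group baseline + *centered* covariate effects + planted
  effects + Gaussian noise (default SD 300 mm³, chosen so total GMV SD
  approximates the published 350–400 mm³). Planted effects are configurable
  per group/behavior/outcome on either the first-pivot-coordinate scale
  (γ-type) or the absolute-minutes scale; defaults emulate the published
  magnitudes (MVPA γ = 375.3 in obesity I, SED γ = −1838.4 in overweight,
  right hippocampus).
* Epoch series reproduce a participant's daily minutes exactly (after
  largest-remainder integer rounding, hence the ±1 min round-trip
  guarantee), with sleep split into an early-morning and an end-of-day
  block and optional non-wear gaps.

What it does **not** emulate: day-to-day behavior variability (every
generated day repeats the daily average), seasonal or weekday/weekend
behavior differences, measurement error in the sleep log, non-Gaussian
outcome tails, or any real spatial structure in MRI segmentation. A green
test therefore establishes that the estimators recover what the stated
world plants — not that the published effects are true, which no analysis
of synthetic data could show.

## Numerical choices

* Closure tolerance 1e-9; ilr round-trip verified to 1e-9.
* OLS via `stats::lm` (QR); rank deficiency is an explicit error naming the
  collinear column. Tests compare coefficients against a brute-force
  normal-equations solver to 1e-8.
* NIPALS weight vectors are normalized each step; extraction stops when the
  residual response norm falls below 1e-10 of the original.
* Monte-Carlo splits are drawn once per plan from its seed, so CV curves and
  SR intervals are bit-reproducible.
* Ties at the 1-SE rule resolve to the smaller component count (parsimony).

## Limitations

* The moderation screen at α = 0.15 is a screen, not a test; stratified
  estimates inherit the small group sizes (23–41) and should be read with
  the same caution the design warrants.
* Percentile SR intervals from 50 % training splits are wider than
  full-sample intervals would be; they describe split-to-split stability.
* The generator's covariate distributions are independent within group
  (e.g. height and weight are linked only through BMI), which is simpler
  than reality but irrelevant to the estimands tested.
* The pipeline consumes GMV as tabular input; image processing and
  segmentation are out of scope.
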