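# movecomp

Compositional and multivariate pattern analysis of 24-hour movement
behaviors.

## The problem

A day is a closed budget: sleep, sedentary time (SED), light physical
activity (LPA) and moderate-to-vigorous physical activity (MVPA) must sum to
1440 min. Accelerometer-derived behavior variables are therefore
co-dependent ("closure") and strongly collinear, and naive regressions of a
health outcome on one behavior ignore that adding minutes to it necessarily
removes them from another. `movecomp` implements, for cohorts of children
with overweight/obesity and hippocampal gray-matter volume (GMV, mm³) as the
outcome, the full analytical chain this kind of study needs:

* **Accelerometer reduction** — epoch-level ENMO magnitudes (m*g*) are
  classified with non-dominant-wrist thresholds (SED < 35, LPA 35–200,
  MVPA > 200 m*g*) and binned into a 33-band × 25 m*g* awake intensity
  spectrum; non-wear epochs are imputed from the same clock time on other
  days; days are combined as (weekdays × 5 + weekends × 2) / 7; participants
  need ≥ 4 valid days (≥ 16 h wear) including a weekend day.
* **Standard linear models** — GMV on absolute minutes of one behavior plus
  covariates (sex, peak-height-velocity offset, parental university
  education, total brain volume), with a weight-status moderation screen
  (joint F-test, α = 0.15) that triggers stratified fits.
* **Compositional data analysis** — isometric log-ratio *pivot coordinates*:
  coordinate *k* of a D-part composition is
  `sqrt((D−k)/(D−k+1)) · ln(x_k / gmean(x_{k+1..D}))`. The γ coefficient of
  the first coordinate estimates the association of one behavior *relative
  to* all remaining behaviors; isotemporal-substitution curves translate γ
  into the predicted GMV change when δ min/day move from one behavior to
  another.
* **Multivariate pattern analysis** — PLS1 regression of the (covariate-
  residualized) outcome on all 33 collinear spectrum bands jointly;
  Monte-Carlo cross-validation (default 1000 repetitions, 50 % holdout)
  selects the component count; *target projection* compresses the model into
  one predictive component; per-band *selectivity ratios*
  `SR_j = sign(p_tp,j) · var(explained x_j)/var(x_j) ∈ [−1, 1]` describe the
  association pattern across intensities, with percentile CIs from the
  resampling splits.
* **Synthetic cohorts** — since no participant-level data are public, a
  seeded generator emulates the study design: 93 children in three
  weight-status groups (23/41/29), logistic-normal compositions closing to
  1440 min with realistic dispersion and inter-behavior correlations,
  covariates, intensity spectra, epoch-level series, and outcomes with
  configurable planted compositional or absolute effects.

## Worked example

```r
library(movecomp)

cfg    <- generator_config(n_participants = 93, seed = 2020)
cohort <- generate_cohort(cfg)

describe_cohort(cohort)$percent_of_day
#>    sed    lpa   mvpa in_bed
#>     39     19      4     38

ob1 <- cohort[cohort$weight_status == "obesity I", ]
fit_absolute(ob1, "mvpa", "gmv_right_hippocampus")
#> Absolute-minutes fit: mvpa -> gmv_right_hippocampus
#>   B = 5.619  95% CI [1.744, 9.494]  p = 0.005762  (n = 41)

fit <- fit_compositional(ob1, "mvpa", "gmv_right_hippocampus")
fit
#> Compositional fit: mvpa relative to remaining behaviors -> gmv_right_hippocampus
#>   gamma = 392.60  95% CI [53.48, 731.71]  p = 0.02464  (n = 41)

substitution_curve(fit, donor = "sed", receiver = "mvpa", deltas = c(0, 10, 20))
#>   delta  estimate  ci_lower ci_upper
#> 1     0   0.00000  0.000000   0.0000
#> 2    10  55.82733  5.854115 105.8005
#> 3    20 103.36945 10.368217 196.3707

pls_spectrum_analysis(ob1, "gmv_right_hippocampus",
                      plan = mc_cv_plan(100, 0.5, seed = 7))$cv
#> Monte-Carlo CV: 1 component(s) selected
```

Reading the output: the cohort spends 39 %, 19 % and 4 % of the day in SED,
LPA and MVPA (38 % in bed). In the obesity-I stratum each extra daily MVPA
minute, taken in isolation, is associated with B ≈ 5.6 mm³ more right-
hippocampus GMV; relative to a proportional decrease of the remaining
behaviors the association is γ ≈ 393 mm³ per unit log-ratio; and moving
20 min/day from SED to MVPA predicts ≈ 103 mm³ (≈ 3 % of the stratum mean)
more GMV. These match the effect magnitudes the default generator plants.

A full configured run (descriptives, correlations, all three model families,
stratified, with CSV/figure outputs and a reproducibility manifest):

```r
run_pipeline(run_config(generator = cfg, mc_reps = 100, seed = 11,
                        out_dir = "movecomp_run"))
```

or from the shell: `Rscript inst/cli/movecomp.R run --config run.yaml`.

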