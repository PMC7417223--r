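---
title: "Methods: allometric mass estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric mass estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mothmass` estimates moth dry body mass from forewing length with a linear
mixed model on the natural-log scale,

$$\ln M_{ij} = (\beta_0 + \beta_{0,f}) + (\beta_1 + \beta_{1,f})\,\ln L_{ij}
  + u_s + \varepsilon_{ij},\qquad
  u_s \sim N(0, \sigma^2_s),\ \varepsilon_{ij} \sim N(0, \sigma^2_e),$$

with $M$ in milligrams, $L$ in millimetres, a random intercept $u_s$ per
species, and fixed adjustments $\beta_{0,f}, \beta_{1,f}$ per family group.
The log-log form is the standard allometric power law
$M = e^{\beta_0} L^{\beta_1}$; the species random intercept absorbs
species-level departures from the family line (body-plan differences,
sampling date effects) so that the fixed effects describe the family-level
scaling that prediction needs. The model assumes multiplicative lognormal
errors — reasonable for masses spanning roughly 1 to 750 mg — and a common
residual variance across families.

### Candidate structures and selection

Three predictor structures can be fitted with `fit_mixed_allometry()` and
compared with `select_structure()`:

* `linear`: $\ln M \sim L \times \mathrm{group}$,
* `loglog`: $\ln M \sim \ln L \times \mathrm{group}$,
* `segmented`: $\ln M \sim (L + (L-\psi)_+) \times \mathrm{group}$, a single
  broken-stick bend shared across groups.

All three keep $\ln M$ as the response, so their BICs are directly
comparable; only the predictor transform differs. Every model is fitted by
**maximum likelihood, not REML**: BIC comparison and likelihood ratio tests
across different fixed-effect structures are only valid under ML. The BIC is
computed as $-2\ell + k\ln n$ with $k$ counting all fixed effects, both
variance components, and (for the segmented structure) the breakpoint.

The breakpoint $\psi$ is estimated by a profile-likelihood grid search over
the observed unique forewing lengths, excluding the three smallest and three
largest so both segments retain support. It is counted as one parameter in
$k$. A shared breakpoint (rather than one per family) keeps the structure
identifiable in family groups with few individuals; at extreme candidate
values the hinge can become collinear with the length term inside a group,
in which case the rank-deficient column is dropped for that candidate only.

### Family grouping

Family-specific parameters are only trustworthy where several species
support them, so `group_families()` pools families represented by fewer than
five distinct species into a single `"other"` group (the threshold is an
argument; five is the default because species, not individuals, carry the
between-species information that family slopes are estimated from). The
pooled group is the treatment-coding reference level, which makes the fitted
coefficients literally "adjustments to be added to the other-families
parameters" — the layout `extract_parameters()` exposes and the packaged
reference file uses. Predictions for families never seen in training fall
back to the pooled parameters with a warning rather than an error, because
historical abundance datasets routinely contain such families.

### Degenerate and edge cases

* Species random-intercept variance estimated at zero (a singular fit) is
  accepted with a warning; it is a boundary estimate, not a failure.
* With a single family group the group terms are dropped and the
  interaction LRT degenerates to $\chi^2 = 0$ with zero degrees of freedom
  and $p = 1$.
* `marginal_r2()` implements the Gaussian variance partition
  $\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\sigma^2_s +
  \hat\sigma^2_e)$ on the ln scale.

## Prediction

`predict_mass()` exponentiates the fixed-effect linear predictor. Species
without measurements are predicted at the **arithmetic midpoint** of their
published field-guide forewing range (`species_expected_mass()`); the
midpoint is taken on the millimetre scale before logging, matching how such
ranges are quoted. Sample biomass (`sample_biomass()`) is the
abundance-weighted sum of species predictions, with a sample defined as all
moths captured at one site on one day, across traps — trap identity is
deliberately dropped because historical schemes rarely preserve it.

No uncertainty interval accompanies a single-moth prediction: the packaged
parameters are point values, and pipeline-level uncertainty is what the
bootstrap machinery measures.

## Validation machinery

### Major Axis regression

Measured and predicted biomass both carry error and neither is controlled,
so ordinary least squares would attenuate the slope; `major_axis_fit()`
therefore uses model II regression with the Major Axis criterion (the first
principal axis of the covariance matrix). The exact 95% slope CI follows
Jolicoeur's angle method: with eigenvalues $\lambda_1 \ge \lambda_2$ and
$H = F_{1-\alpha;1,n-2} \big/ \big[(\lambda_1/\lambda_2 +
\lambda_2/\lambda_1 - 2)(n-2)/4\big]$, the limits are
$\tan(\theta \pm \tfrac12 \arcsin\sqrt{H})$ around the axis angle $\theta$.
This is algebraically identical to inverting the $F$ test that the
residual-axis and major-axis scores are uncorrelated, and the test suite
cross-checks the slope against an independent eigendecomposition oracle.

Validation regressions are run on the **natural-log scale** of both axes.
Masses span nearly three orders of magnitude; on the raw scale a single
large species would dominate the perpendicular distances, and the
characteristic behaviour that excluding small species (measured mean
> 15 mg) restores a 1:1 slope only arises when small species carry leverage,
i.e. on the log scale. The 15 mg threshold is applied to the measured
species mean, strictly greater-than.

Significance is a one-tailed permutation test (`ma_permutation_p()`):
permute $y$ against fixed $x$, statistic = Pearson correlation, add-one
convention $p = (1 + \#\{r_\pi \ge r_{obs}\})/(n_\pi + 1)$, default 100
permutations, so the smallest attainable $p$ is $1/101 \approx 0.0099$.
"Significant" in bootstrap summaries means $p \le 0.05$.

### Train/test bootstrap

`bootstrap_validation()` draws, per replicate, a training subset without
replacement (default 480 of 600 individuals, an 80/20 split), refits the
simplified log-log model, and validates on the held-out individuals whose
species are predicted from field-guide midpoints. Two design choices matter:

* the family grouping is **re-derived from each training subset**, so no
  information about test-set family richness leaks into training; test
  species from families not retained in training are predicted through the
  pooled parameters;
* a single master seed spawns one RNG substream per replicate, so results
  are reproducible and independent of evaluation order. Replicates whose
  fit or validation degenerates are logged and redrawn, never silently
  dropped.

### Prediction error versus sample size

`prediction_error()` normalises the percentage error of a sample's
predicted biomass by the whole-dataset offset (computed by
`dataset_prediction_offset()`, never hard-coded), so a large random sample
has expected error zero. `error_vs_sample_size()` resamples individuals
with replacement over a grid of sample sizes (default 10–1000 in steps of
10, 1000 replicates each) and summarises mean, standard error and range of
the error within sample-size windows of 100.

## The synthetic generator

`simulate_community()` exists to give the statistics a known truth. It
emulates: per-family log-log allometry (defaults equal to the packaged
reference parameters), species random intercepts (SD 0.2), individual
residual noise (SD 0.3), species mean lengths log-uniform on 7–35 mm
(within the observed 7–40 mm span of the training data), within-species
length variation (CV 0.05), measurement quantization (1 mm, 0.01 mg with a
0.005 mg detection floor), symmetric field-guide ranges (half-width 2 mm,
with an optional mean-shift knob, default off, to emulate guides based on
larger historical specimens), and a 3-site × 15-date sample grid with
lognormal species abundances (sdlog 1) allocated multinomially — skewed
counts typical of light traps, without the extra parameter a negative
binomial would add. The default community has 94 species in 11 families
(36/22/11/10 in the four rich families, 15 species across seven small
ones) and 600 individuals, the scale of the reference training data.

It does **not** emulate: sexual dimorphism, phenology, geographic or
temporal body-size drift, asymmetric guide errors, or any real
species-abundance-distribution theory. Passing tests on synthetic data
therefore demonstrate that the estimators recover the generating process at
realistic scale and noise — not that the lognormal/random-intercept
assumptions hold for any particular field dataset.

`recovery_experiment()` runs the full pipeline over many simulated
datasets and reports bias, RMSE, standard error of the mean estimate and
Wald 95% CI coverage per fixed effect.

## Numerical choices

* Optimizer: `bobyqa` through lme4, with derivative recomputation disabled
  (fixed-effect covariance comes from the factorised system, not the
  optimizer Hessian).
* Singular fits ($\hat\sigma^2_s = 0$) warn; failure to converge errors.
* Natural logarithms throughout.
* Ties in BIC selection break toward fewer parameters.
* Species-aggregate taxa ("Common Rustic agg.") are single species
  identifiers; species-to-family mapping must be unique and is validated.
* Below-detection masses are written to CSV as the sentinel `"<0.005"`, not
  zero, so the exclusion filter is testable from files.
* Per-replicate and per-dataset seeds are drawn as 31-bit integers from the
  master seed.

## Problem sizes used in the shipped analyses

The test suite and `scripts/acceptance.R` run the expensive analyses at
sizes chosen to make their statistical claims at desk scale: 200 simulated
datasets for parameter-recovery coverage and for LRT type-I-error
calibration, 200 bootstrap replicates, error curves over sizes 10–300 with
100 replicates per size, 500 null permutation tests for the uniformity
check, and 1000 random datasets for the Major Axis oracle comparison. The
full-scale defaults (10,000 bootstrap replicates; sizes to 1000 with 1000
replicates) remain the function defaults for real analyses.

## Known limitations

* The packaged parameters were trained on a mid-summer, northern-England
  light-trap sample dominated by mid-sized macro-moths; predictions for
  very small (< ~5 mm) or very large (> ~40 mm) forewings, day-flying
  families, or non-UK faunas are extrapolations.
* No sex covariate: dimorphic species get a single average prediction.
* The Wald CIs used for coverage reporting ignore variance-component
  uncertainty; at 94 species this is a minor effect, visible as coverage a
  shade below nominal.
* Field-guide ranges are treated as error-free inputs; a systematic
  guide-versus-contemporary size shift propagates directly into predicted
  masses (the generator's mean-shift knob lets you quantify that
  sensitivity).
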