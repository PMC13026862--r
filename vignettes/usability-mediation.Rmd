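---
title: "Methods: Bayesian mediation and equity analysis of mHealth usability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian mediation and equity analysis of mHealth usability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usabmed)
```

## The scientific question

Mobile-health interventions for type-2 diabetes show heterogeneous clinical
benefit, and one candidate mechanism is perceived usability: an application
that is easy to operate lowers friction for self-management behaviours,
which can translate into measurable cardiometabolic change. `usabmed`
implements a complete analysis pipeline for a small (n ≈ 22) single-arm
cohort that used a diabetes self-management app for 90 days: usability
scoring with the 16-item Computer System Usability Questionnaire (CSUQ),
a Bayesian mediation model in which interface quality transmits part of the
age effect on systolic blood-pressure change, usability-stratified outcome
description, an item-level educational-equity analysis, and a robustness
suite. A synthetic-trial generator with known structural ground truth makes
every stage testable.

## CSUQ scoring

The CSUQ has 16 items on a 1–7 agreement scale: system quality (items
1–6), information quality (7–12), interface quality (13–15) and overall
satisfaction (item 16). Dimension scores are means of constituent items and
the overall score is the mean of all 16 items (`score_csuq()`). Overall
scores classify participants into usability strata: high (≥ 6), low (< 5),
moderate otherwise. A published band of "5–5.9" for moderate leaves scores
in (5.9, 6) — attainable as 16-item means, e.g. 95/16 — unassigned;
`classify_stratum()` defines moderate as the half-open interval [5, 6) so
the three strata partition [1, 7].

Missing items: a dimension score is computed when more than half of its
items are answered, the overall score when at least 12 of 16 are answered
(both thresholds configurable). This is the usual instrument-scoring
convention; an analysis restricted to complete questionnaires can be
reproduced by filtering on `n_answered == 16` before scoring.

## The mediation model

Two Gaussian linear equations with exposure $X$ (age, years), mediator $M$
(a CSUQ dimension score) and outcome $Y$ (90-day clinical change):

$$M_i = \alpha_M + a X_i + \gamma' C_i + \varepsilon_{M,i}, \qquad
  Y_i = \alpha_Y + b M_i + c' X_i + \delta' C_i + \varepsilon_{Y,i},$$

with covariates $C$ (sex, education on its ordinal scale, baseline systolic
pressure by default) and independent Gaussian errors. Per posterior draw,
the indirect effect is $a \cdot b$, the direct effect $c'$, and the total
effect $c' + a b$ — an exact identity on every draw, which the tests assert
bitwise. The mediated proportion is reported as the ratio of posterior
means $\mathbb{E}[ab]/\mathbb{E}[c' + ab]$; the draw-wise ratio is
unstable when the total effect crosses zero, so its credible interval uses
only draws with $|c' + ab| > 10^{-6}$ and the sign of the mean total
effect, with the retained fraction reported alongside.

### Priors

Slope priors are elicited from literature-scale correlation evidence with
`slope_prior_from_correlation()`: a correlation $r$ with predictor and
response SDs $s_x$, $s_y$ implies a slope $r\,s_y/s_x$; the prior location
is the midpoint of the implied slope range and the scale is an analyst
judgment. The default set (`default_prior_set()`):

* path a: Normal(0.015, 0.08) interface points per year — a correlation
  band of 0.10–0.20 with age SD 10 y and interface SD 0.8 implies
  0.008–0.016 per year; the scale 0.08 deliberately lets the data dominate;
* path b: Normal(−1.5, 0.6) mmHg per interface point, derived from
  adherence-mediated blood-pressure effects of 1–2 mmHg;
* direct path c′: Normal(−0.2, 0.15) mmHg per year, weakly informative;
* covariate coefficients Normal(0, 1), intercepts Normal(0, 50), residual
  scales half-Student-t(3, 0, 10).

The source literature states these priors inconsistently in places (scales
of 0.008 vs 0.08 for path a; path b quoted per decade but fitted per
point; a sign flip on the age–usability correlation between sections). The
defaults above resolve those conflicts in favour of unit consistency with
the reported posteriors, and every prior is overridable or replaceable via
YAML (`write_prior_set()`/`read_prior_set()`). The sensitivity variants
are mechanical: `weakened_prior_set()` doubles every scale and moves no
location; `skeptical_prior_set()` centres the three path priors at zero.

### Sampling and diagnostics

The joint posterior factorises over the two equations given the data, so
each equation is sampled by a conditionally conjugate Gibbs chain
(`bayes_lm_gibbs()`): coefficients from their multivariate-normal full
conditional, the residual variance from its inverse-gamma full conditional
using the scale-mixture representation of the half-Student-t prior. The
contract is distributional, not algorithmic — any correct sampler passes
the same oracle suite (conjugate closed form, flat-prior agreement with
least squares, parameter recovery on generator truth, null coverage).
Predictors are mean-centred internally for conditioning; coefficients are
reported on original units.

Convergence is assessed with split-chain Gelman–Rubin statistics and an
autocorrelation effective sample size (Geyer initial monotone positive
sequence); a run with any path-parameter R-hat ≥ 1.01 is flagged with a
warning and `attr(draws, "converged") = FALSE`, never passed silently.
The desk profile is 4 chains × 2,500 iterations (500 warmup; 8,000
retained draws), which yields Monte-Carlo errors far below the posterior
scales of this model; `mcmc_profile("paper")` switches to 4 × 25,000 with
5,000 warmup for full-length runs.

## Stratified outcomes

`stratified_table()` summarises each 90-day change per usability stratum
and computes a high-versus-low Cohen's d (pooled SD with $n-1$ weights;
Hedges' small-sample correction optional) with a bias-corrected and
accelerated (BCa) bootstrap interval: bias correction from the share of
replicates below the point estimate, acceleration from jackknife skewness,
resampling within strata, 10,000 replicates by default (2,000 in the test
profile). Forcing both corrections to zero reduces the interval exactly to
the percentile interval, which the tests exploit as a reduction oracle; a
bias-correction-only mode is provided because "bias-corrected bootstrap"
is ambiguous in common usage. Strata smaller than 6 are flagged
descriptive-only, and no between-stratum hypothesis tests are run — the
stratification is a descriptive complement to the continuous mediation
analysis, not an inferential endpoint.

## Item-level equity analysis

`disparity_table()` compares each CSUQ item between participants with at
most primary education and everyone else, using pooled-variance t-tests by
default (Welch optional), Holm step-down adjustment across the full
16-item family, and per-item Cohen's d. A covariate-adjusted sensitivity
analysis refits each item by least squares on the education indicator plus
age and baseline severity, with Holm re-applied, and is reported
separately. `power_simulation()` estimates the power of this two-group
design by direct Monte Carlo against a configurable effect size, group
sizes and level; it is validated against the analytic noncentral-t power.

## The synthetic-trial generator

`generate_trial()` emulates the study conditions: n = 22; age Normal(59,
8.1) truncated to [45, 74] by rejection; 86% female; education 41/23/36%
across at-most-primary / secondary / technical-bachelor; baseline BMI,
weight, blood pressures and HbA1c at the study's means and SDs; and the
structural mediation defaults a = 0.12 points/year, b = −1.35 mmHg/point,
c′ = −0.28 mmHg/year. Interface items 13–15 are the structural mediator
plus item noise, rounded and clamped to 1–7; information items carry
additive latent-scale deficits for the at-most-primary stratum (defaults
−1.9, −1.4, −1.1, −1.2 on items 7, 9, 11, 12), reproducing the equity
pattern with controllable size. One master seed drives per-participant
counter-derived streams, so record i is identical whatever the cohort size
— a property the determinism tests check byte-for-byte on the CSV.

Choices worth making explicit:

* **Residual scales.** σ_M = 0.7 interface points (idiosyncratic) and
  σ_Y = 9.5 mmHg were fixed once so the marginal ΔSBP SD lands near the
  study's 10.8 given the configured paths and age spread.
* **Person-level factor.** The study's dimension SDs (0.69–0.81) are
  incompatible with its overall-score SD (0.89) unless dimensions are
  strongly correlated within person; the inter-dimension correlation is
  not published. The generator therefore adds a shared person-level factor
  (SD 0.75, part of the mediator residual and common to all dimension
  latents), calibrated once to the printed overall-score SD; the
  trade-off is per-dimension SDs somewhat above their printed values.
* **Age truncation.** A Normal(59, 8.1) truncated to the printed range
  [45, 74] necessarily has SD ≈ 6.7 — the printed mean, SD and range are
  mutually inconsistent. The generator honours range and mean; the moment
  tests assert the age mean and the untruncated clinical moments.
* **Likert attenuation.** Rounding, clamping and 3-item averaging make
  the observed interface score an error-prone proxy of the structural
  mediator (observed age slope ≈ 0.08 at latent truth 0.12 under the
  defaults). Recovery oracles therefore run on the generator's latent
  trace (`attr(trial, "latents")`), while engine-versus-least-squares
  comparisons use the same observed variable on both routes. This is
  exactly the regression-attenuation caveat that applies to the real
  instrument: passing tests demonstrate correctness of the machinery, not
  immunity of dimension-score mediation estimates to measurement error.
* **Missingness** is generated completely at random at a configurable
  rate (default 0) — the study reports no missingness mechanism.

## Sensitivity suite

`prior_sensitivity()` refits under the default, weakened and skeptical
sets plus the maximum-likelihood equivalent (`ml_mediation()`: least
squares per equation, delta-method interval
$\widehat{\mathrm{Var}}(\hat a\hat b) = \hat a^2 \mathrm{Var}(\hat b) +
\hat b^2 \mathrm{Var}(\hat a)$, percentile bootstrap optional) with a
paired seed policy, and reports the default-versus-ML interval-width
ratio. `loo_influence()` re-estimates the model with each case removed —
by maximum likelihood by default, since n Bayesian refits add Monte-Carlo
noise without changing the influence ranking at this scale; a full
Bayesian mode is available. `covariate_expansion()` refits with additional
covariates (diabetes duration, comorbidity count, medication regimen) and
reports the indirect-effect shift in standard-error units.

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale sizes chosen for tight Monte
Carlo error at interactive cost: 8,000 retained draws for a single fit,
2,000 for replicated fits (coverage and interval-width studies of 100
replicates), 10,000 bootstrap replicates for single intervals and 2,000
inside replicated studies, and 100,000 simulations for power calibration.
Rounding happens only at render time (`render_table()`: two decimals for
scores and effects, whole percents for proportions); all persisted JSON
carries full precision. Degenerate inputs are contractual: zero-variance
t statistics are reported explicitly (0 or signed infinity), a
non-positive residual scale yields a −∞ log posterior rather than an
error, single-chain R-hat is an error rather than a silent 1.0, and
rank-deficient designs fail naming the collinear columns.

## Limitations

The generator emulates marginal moments and the linear mediation
structure, not longitudinal trajectories, app-engagement telemetry,
informative missingness, or the skewness and ceiling effects of real
Likert responses beyond what discretisation induces. Usability is measured
once, at day 90, so mediation estimates — in the real study and on
synthetic data shaped like it — quantify a hypothesised pathway and cannot
establish temporal precedence. Stratum contrasts at n = 22 rest on groups
as small as 3–8 and are reported descriptively with that flag. The
proportion mediated is meaningful only when direct and indirect effects
share a sign; its interval should be read together with the retained-draw
fraction the summary reports.
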