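# usabmed

Bayesian mediation and equity analysis of perceived usability in a
mobile-health diabetes trial.

Mobile-health apps for type-2 diabetes help some patients dramatically and
others not at all. One candidate mechanism for that heterogeneity is
perceived usability: an interface that is easy to operate lowers the
friction of daily self-management, which can show up in cardiometabolic
endpoints. `usabmed` is a research pipeline for a small single-arm cohort
(n ≈ 22) that used such an app for 90 days. It is written for
biostatisticians who want to reproduce, stress-test or extend this style of
small-sample mediation analysis.

The pipeline covers:

* **CSUQ scoring** — the 16-item Computer System Usability Questionnaire
  into system / information / interface / satisfaction dimension scores,
  an overall score, and high (≥ 6) / moderate ([5, 6)) / low (< 5)
  usability strata;
* **prior elicitation** — converting literature correlation ranges into
  Normal slope priors (`slope_prior_from_correlation()`), with default,
  weakened (scales doubled) and skeptical (paths centred at 0) sets;
* **Bayesian mediation** — the two-equation Gaussian model
  `M = α_M + a·age + γ'C + ε_M`,
  `Y = α_Y + b·M + c'·age + δ'C + ε_Y`,
  sampled by conditionally conjugate Gibbs chains, with per-draw indirect
  (`a·b`), direct (`c'`) and total (`c' + a·b`) effects, equal-tailed
  credible intervals, directional posterior probabilities, proportion
  mediated, split-chain R-hat and autocorrelation effective sample size;
* **stratified outcomes** — per-stratum summaries of the 90-day clinical
  changes with Cohen's d and BCa bootstrap confidence intervals;
* **item-level equity analysis** — per-item education contrasts with Holm
  adjustment over all 16 items, covariate-adjusted sensitivity models and
  Monte-Carlo power simulation;
* **robustness** — prior-sensitivity refits, a maximum-likelihood
  equivalent with delta-method intervals, leave-one-out case influence,
  covariate expansion;
* **synthetic trial generator** — study-shaped cohorts with configurable
  structural ground truth (defaults a = 0.12 points/year, b = −1.35
  mmHg/point, c' = −0.28 mmHg/year), used by every test.

The methods vignette (`vignettes/usability-mediation.Rmd`) documents the
model, priors, numerical conventions and generator design in full.

## Worked example

```r
library(usabmed)

cohort <- generate_trial(generator_config(n_participants = 22, seed = 1))
scores <- score_cohort(cohort)
merged <- merge(cohort, scores[, c("id", "interface_quality")], by = "id")

spec  <- mediation_spec(seed = 1)          # default priors, 4 x 2500 draws
draws <- sample_posterior(spec, merged)
summarize_mediation(draws)
```

```
Bayesian mediation summary (8000 draws, 95% CrI)
  a         0.055  [-0.009,  0.117]  P(<0)=0.04
  b        -1.748  [-2.923, -0.616]  P(<0)=1.00
  indirect -0.095  [-0.245,  0.014]  P(<0)=0.95
  direct   -0.260  [-0.530,  0.011]  P(<0)=0.97
  total    -0.356  [-0.653, -0.058]  P(<0)=0.99
  proportion mediated 27% [-5%, 99%]
```

Reading: on this synthetic cohort each additional year of age is associated
with a 0.36 mmHg larger systolic reduction in total, of which 0.10 mmHg
(about a quarter) flows through interface-quality perceptions; the
posterior probability that the mediated path is beneficial (negative) is
0.95. `age_contrast(summarize_mediation(draws), years = 10)` scales this to
the 10-year contrast (3.6 mmHg total, 1.0 mmHg mediated). At n = 22 the
estimates are attenuated relative to the generator's latent truth because
the observed 3-item interface score measures the structural mediator with
error — see the vignette.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` … `06_sensitivity.R`), writing tables and JSON
under `results/`.

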