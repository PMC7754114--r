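---
title: "Methods: anchored indirect treatment comparisons with a real-world arm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored indirect treatment comparisons with a real-world arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchoritc)
```

## The estimand and the anchored design

The package targets contrasts between a trial-only regimen (here labelled
`DRd`) and real-world-only regimens (`VRd`, `Vd`) on progression-free
survival, when both sources contain the shared anchor `Rd`.  Within each
source a Cox proportional-hazards model estimates the direct log hazard
ratio against the anchor; the anchored indirect comparison is the
difference of direct log hazard ratios, with variance the sum of the two
variances, transformed back to the hazard-ratio scale with a
normal-approximation 95% interval (z = 1.96 throughout, matching the
back-out arithmetic used to check published intervals).

Two assumptions carry the design:

1. **Effect-modifier balance across sources.**  Absolute differences in
   prognosis or event ascertainment between trial and routine care cancel in
   the anchored contrast; what does not cancel is a different distribution
   of treatment-effect *modifiers*.  The pipeline addresses this by (a)
   applying a common set of eligibility criteria to both cohorts and (b)
   weighting each real-world treatment group to the trial population.
2. **Independence of the two direct estimates.**  The two real-world direct
   comparisons share the real-world anchor arm, so their errors are
   positively correlated; following standard anchored-comparison practice
   the combination ignores this correlation (each indirect contrast uses one
   trial and one real-world estimate, which are genuinely independent — the
   approximation only matters if indirect contrasts are themselves
   compared).

## Weighting

For each real-world treatment group separately, a logistic model of
trial-membership is fitted on the pooled sample of that group plus the full
trial population (both randomized arms pooled — the randomization makes the
pooled trial covariate distribution the natural target), and each
real-world patient receives the odds weight `w = p/(1 − p)`, normalized to
the group's size.  This is the weight-to-target-population form: the
weighted group mimics the trial's covariate distribution.  The default
membership covariates are the full baseline set (age, sex, race, ISS stage,
cytogenetic risk, ECOG performance status, the creatinine-clearance ≤ 60
mL/min indicator, months from diagnosis to first-line start);
`weighting_set = "demographics_only"` (age, sex, race) reproduces the
sensitivity configuration that omits the clinically important but
frequently missing covariates.  Weights are not truncated by default —
truncation trades variance for bias and nothing in the emulated setting
suggested extreme weights; the effective sample size `(Σw)²/Σw²` is
reported so a collapsing ESS is visible.  Balance is judged by
standardized differences (target-minus-group sign convention; categorical
covariates expanded to indicators); |SMD| > 0.1 is flagged and flags mark
the group for doubly robust estimation (weighting plus outcome-model
covariate adjustment), which protects consistency if either the weight
model or the outcome model is right.

## Survival modelling

The primary outcome convention is **on-treatment**: follow-up is censored
when treatment stops for a reason other than progression or death, because
routine-care patients discontinue for many reasons trial patients do not,
and the anchored design works best when the compared exposures are alike.
**Intent-to-treat** (discontinuation ignored) is the sensitivity
convention.  All times are capped at 48.5 months (the trial's maximum
follow-up), with events beyond the cap reset to censored; 41.4 months is
the analogous overall-survival window.

Cox models use Breslow tie handling (the simulator produces continuous
times, but imported data may tie).  Weighted fits report a robust sandwich
standard error with weights treated as fixed — conservative relative to
accounting for weight estimation — while unit-weight fits use the
model-based variance.  The fits are delegated to `survival::coxph`; the
test suite verifies the contract against an independent hand-written
Breslow partial likelihood maximized by grid search over β ∈ [−5, 5] at
step 1e-4 on datasets of up to eight subjects (including a four-subject
configuration whose maximum is exp(β) = √2 in closed form), at tolerance
1e-3.  Monotone-likelihood situations (no events in an arm, constant
treatment indicator, diverging coefficient) are signalled as errors, never
returned as estimates.

The proportional-hazards diagnostic tests a time-varying treatment effect
of the form β(t) = β + θ·log(t).  It is computed as the Schoenfeld-residual
score test (log-time transform) rather than a Wald test in an
episode-split extended model: the split model needs one row per
subject-by-event-time and becomes quadratic in memory, and a bounded split
grid distorts the test's calibration at large sample sizes, while the
score test is exact, linear in n, and tests the same alternative.  The
subgroup analysis (age ≥ 75 by default) uses a single model with
treatment, subgroup and their interaction — stratum hazard ratios come
from the interaction parameterization and the interaction Wald p is
reported; covariate adjustment is allowed there because within-stratum
balance is not guaranteed by weighting the full cohorts.

## Missing data

Baseline covariates are multiply imputed by chained equations: each
incomplete covariate is modelled on all other baseline covariates plus the
event indicator, log follow-up time and source — the standard predictor
set for imputation feeding a survival model.  Continuous covariates use
predictive-mean matching with k = 5 donors and a Bayesian draw of the
regression coefficients, so imputed values are always observed donor
values (robust to skewed labs such as creatinine clearance); binary and
multi-level categoricals are drawn from fitted logistic/multinomial
probabilities.  Ten cycles and m = 10 datasets are the defaults —
conventional values, exposed in the config; convergence is not formally
tested.  Covariates are imputed in order of increasing missingness.
Degenerate inputs (a covariate 100% missing, a single-level categorical,
no fully observed covariate) are rejected up front.

Analyses run per imputed dataset through weighting, survival and the
anchored combination; the per-dataset indirect log hazard ratios and
variances are then pooled by Rubin's rules (point = mean; total variance =
within + (1 + 1/m)·between; small-sample degrees of freedom; t-based
interval).  Pooling after combining is the default because the combination
is linear on the pooling scale; `pool_before_combine = TRUE` gives the
alternative order, which differs only through the nonlinear
variance-to-interval step.  Weights are re-estimated within each imputed
dataset (the conservative choice; a single stacked estimation would
understate between-imputation variability).  When no cell is missing the
imputation stage is skipped and the "pooled" estimate is the
single-dataset estimate, which is the m → 1 limit of the rules.

## What the generator emulates — and what it does not

`simulation_config()` defaults encode the emulated study's conditions:

- **Covariate marginals** follow the published baseline table of the
  weighted populations: age N(74.3, 5.3); 48% female; 3.5% Black; ISS
  I/II/III 28/43/29%; 14% high-risk cytogenetics; ECOG 0/1/2 35/49/16%;
  creatinine clearance lognormal(log 64, 0.35) giving ~41% ≤ 60 mL/min;
  diagnosis-to-treatment interval gamma with mean 1.4 and SD 1.8 months.
- **Event times** are Weibull proportional-hazards with shape 1
  (exponential) and scale 46 months, chosen for closed-form inversion
  sampling and an anchor-arm median near 32 months, in line with the
  trial's Rd arm; no baseline hazard is published, so the law is a
  modelling choice, and the shape is configurable.
- **True effects** default to log(0.54), log(0.80), log(1.14) vs the
  anchor — the published direct estimates, used as plausible truths for
  parameter-recovery testing, not as reproductions.  Prognostic main
  effects and treatment-by-covariate interactions default to zero: with
  nonzero prognostic heterogeneity the marginal Cox hazard ratio is
  non-collapsible and the configured values would no longer be the
  marginal estimands being recovered.  Both coefficient sets are config
  knobs, and the property tests switch them on deliberately.
- **Real-world structure**: covariate means are shifted modestly
  (older, worse performance status, later stage), treatment assignment is
  a multinomial logit on centered covariates with intercepts matching the
  570/432/358 regimen shares, and patients are spread over 40 clinics of
  lognormal size.  Discontinuation is an independent exponential process
  with rates ordered triplet > doublet (0.055/0.045/0.035 per month
  real-world; ~0.006–0.008 in the trial) and loss to follow-up is higher
  in the real-world source (0.012 vs 0.002 per month), so mean on-treatment
  follow-up lands near 11 real-world months vs ~25 trial months, matching
  the published follow-up asymmetry.  Administrative cap: 48.5 months.
- **Missingness** defaults to the published real-world rates (race 8%,
  labs 20%, cytogenetic risk 30%, ECOG 40%, ISS 47%) and 13% trial
  cytogenetic risk, missing at random given age and sex (the
  always-observed covariates); the intercept of the MAR model is solved
  numerically so realized rates hit their targets in expectation.  An
  event-detection probability per source exists as a knob but defaults to
  1 — no published value constrains it.

What passing tests on these cohorts cannot show: the generator draws
independent records from clean parametric laws, so it says nothing about
informative censoring beyond the modelled processes, about clinic-level
clustering of outcomes (clinics only size the follow-up-restriction
sensitivity), about measurement error or misclassification of real-world
progression beyond a uniform detection probability, or about unmeasured
effect modifiers — the assumption the anchored design itself cannot test.

## Numerical choices and problem sizes

Ties are broken by Breslow's approximation; continuous simulation times
make ties measure-zero, so no jitter is applied.  Logistic separation in
the membership model is detected (non-convergence, |coef| > 15, or NA
coefficients) and reported with the offending covariate named.  Weighted
variances use the `Σw(x − m)²/(Σw − 1)` form with normalized weights.
YAML round-trips write doubles at 17 significant digits so a reloaded
config reproduces a run bit-for-bit.

The test suite sizes its simulations to make each claim sharp but cheap:
parameter-recovery and coverage use 200 replicates at 500 patients per arm
and per regimen; the balance property uses 100 simulated configurations at
500 per group with randomized moderate shifts (|SMD| ≤ 0.4); oracle
equivalence uses exhaustive grid search on ≤ 8-subject datasets; null
calibration of the proportional-hazards test uses 200 replicates of 160
subjects.  These sizes are the package's own trade-off between Monte-Carlo
resolution and a suite that runs in about a minute.

## Known limitations

- The anchored combination ignores anchor-arm correlation between the two
  real-world direct estimates (documented approximation above).
- No multilevel imputation by clinic; no imputation of outcomes.
- No entropy-balancing or method-of-moments matching weights; odds weights
  from a logistic membership model are the single implemented estimator.
- No time-varying covariates, stratified baseline hazards, or network
  meta-analysis beyond the two-source anchored design.
- Published direct hazard ratios from the emulated study are not
  reproducible here — the underlying patient-level data are
  access-restricted — so all end-to-end validation is property-based on
  synthetic cohorts, plus exact reproduction of the published *indirect*
  arithmetic from the published direct estimates.
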