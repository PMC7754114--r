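# anchoritc

Anchored indirect treatment comparisons of survival outcomes across a
randomized trial and a real-world cohort.

## The problem

In transplant-ineligible newly diagnosed multiple myeloma, the triplet
daratumumab–lenalidomide–dexamethasone (D-Rd) was compared against
lenalidomide–dexamethasone (Rd) in a randomized trial, but never head-to-head
against the other common first-line regimens,
bortezomib–lenalidomide–dexamethasone (VRd) and bortezomib–dexamethasone
(Vd).  Those regimens are, however, observable in electronic-health-record
cohorts that also contain an Rd group.  When two data sources share a
comparator, the **anchored indirect treatment comparison** (Bucher method)
estimates the missing contrast on the log hazard-ratio scale:

```
log HR(A vs B) = log HR(A vs anchor) − log HR(B vs anchor)
SE²            = SE²(A vs anchor)    + SE²(B vs anchor)
```

Because only *relative* effects cross sources, differences in absolute event
rates or outcome ascertainment between trial and routine care cancel — but
the two populations must be balanced on treatment-effect modifiers.  The
package implements the full pipeline that makes that assumption defensible:

- **synthetic cohorts** (`simulation_config`, `simulate_cohorts`): paired
  trial and real-world progression-free-survival cohorts with confounded
  real-world treatment assignment, Weibull proportional-hazards outcomes,
  competing censoring processes (administrative cap, loss to follow-up,
  treatment discontinuation) and missing-at-random covariates;
- **eligibility** (`apply_eligibility`): harmonized trial-style
  inclusion/exclusion with first-failure attrition accounting;
- **imputation** (`impute_chained`, `pool_rubin`): chained-equations multiple
  imputation (predictive-mean matching + categorical draws) and
  Rubin's-rules pooling;
- **weighting** (`fit_membership_model`, `odds_weights`, `balance_report`):
  propensity-score odds weights that reweight each real-world treatment
  group to the trial population, with standardized-difference diagnostics
  (|SMD| > 0.1 flagged);
- **survival** (`derive_outcome`, `fit_cox`, `ph_check`,
  `subgroup_interaction`): on-treatment vs intent-to-treat outcome
  conventions and weighted Cox models with robust variance;
- **itc** (`se_from_ci`, `bucher_combine`, `percent_risk_reduction`): the
  anchored combination, including back-out of log-scale standard errors from
  published confidence intervals;
- **pipeline** (`run_config`, `run_pipeline`): one-call orchestration of the
  primary analysis and the prespecified sensitivity analyses (intent to
  treat, doubly robust, demographics-only weighting, follow-up restrictions,
  age ≥ 75 subgroup).

## Worked example

Combining the published direct comparisons (D-Rd vs Rd in the trial,
HR 0.54, 95% CI 0.42–0.71; VRd vs Rd in the real-world cohort, HR 0.80,
95% CI 0.62–1.02) through the shared Rd anchor:

```r
library(anchoritc)
a <- hr_estimate("DRd", "Rd", hr = 0.54, ci = c(0.42, 0.71), source = "trial")
b <- hr_estimate("VRd", "Rd", hr = 0.80, ci = c(0.62, 1.02), source = "rwd")
itc <- bucher_combine(a, b)
itc
#> Anchored indirect comparison: DRd vs VRd (anchor Rd)
#>   HR 0.68 (95% CI 0.47, 0.97), p = 0.033
percent_risk_reduction(itc)
#> [1] 32
```

The combined hazard ratio of 0.68 says the triplet roughly takes a third off
the instantaneous risk of progression or death relative to VRd, and the
interval excluding 1 makes the contrast significant at the 5% level even
though neither input involved a head-to-head trial.

A full synthetic run at the study's sample sizes (the direct and indirect
estimates scatter around the configured truths of 0.54 / 0.80 / 1.14 within
sampling error; the balance report shows the weighting doing its job):

```r
cfg <- run_config(
  sim = simulation_config(n_trial_per_arm = 358,
                          n_rwd_per_regimen = c(VRd = 570, Rd = 432, Vd = 358),
                          seed = 7),
  m = 10, seed = 7)
art <- run_pipeline(cfg)
art
#> Anchored ITC run artifact [primary_on_treatment]
#>   1853 eligible patients; 10 imputation(s)
#> Direct comparison: DRd vs Rd (trial, unadjusted)
#>   HR 0.65 (95% CI 0.52, 0.81), p = 0.00014
#>   n = 680, events = 319
#> Direct comparison: Vd vs Rd (rwd, weighted)
#>   HR 1.19 (95% CI 0.87, 1.63), p = 0.28
#>   n = 709, events = 193
#> Direct comparison: VRd vs Rd (rwd, weighted)
#>   HR 0.80 (95% CI 0.58, 1.10), p = 0.16
#>   n = 818, events = 183
#> Anchored indirect comparison: DRd vs Vd (anchor Rd)
#>   HR 0.55 (95% CI 0.37, 0.80), p = 0.0021
#> Anchored indirect comparison: DRd vs VRd (anchor Rd)
#>   HR 0.82 (95% CI 0.55, 1.21), p = 0.31
max(abs(art$balance$smd_weighted))
#> [1] 0.038
```

A thin command-line wrapper over the same function lives at
`inst/scripts/run-pipeline.R` (YAML config in, delimited tables + JSON
manifest out).

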