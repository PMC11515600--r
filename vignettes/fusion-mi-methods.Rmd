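---
title: "Data fusion with multiple imputation for misclassification-corrected case-control analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data fusion with multiple imputation for misclassification-corrected case-control analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemi)
```

## The problem

A case-control analysis of a rare outcome (the motivating application is
homicide victimization) compares exposure odds between a case registry and a
population control survey.  The registry measures the exposure — recent
cannabis and alcohol use — by toxicological blood testing; the control survey
only asks about it.  Self-report is misclassified relative to the biomarker,
and differentially so: self-reported cannabis use has high specificity but
low sensitivity (a positive blood test is often not reported), self-reported
alcohol use the reverse (past-month drinking is reported far more often than
a blood test is positive), and both error rates vary by demographics.
Modelling the two measurements as if they were the same variable therefore
biases the exposure odds ratios.

`fusemi` implements the data-fusion correction.  A third system — a
*validation survey* of drivers with **paired** self-report and biomarker
measurements — is harmonized and stacked under the control survey.  The
control survey's never-measured biomarker columns become missing data, imputed
by chained equations under a missing-at-random assumption.  The completed
control survey is then combined with the (separately imputed) case registry
and analysed by survey-weighted logistic regression.  Because the validation
survey participates in the imputation but not in the post-imputation
analysis, Rubin's rules overstate the variance; valid inference uses
*bootstrap with multiple imputation* (BMI): resample first, impute M times
within each bootstrap replicate, and pool the B x M estimates by a one-way
ANOVA decomposition with Satterthwaite degrees of freedom.

## The synthetic study

No public version of the three real systems exists, so the package ships a
generator (`sim_config()`, `simulate_systems()`) whose defaults encode the
study conditions and whose latent truth makes every downstream stage
testable.

* **Demographics** are drawn from the control-survey margins of the source
  study (age 8.8/24.0/24.7/24.7/17.8% across the five groups, 48.2% male,
  race 65.5/11.8/15.2/7.5%, education 12.9/28.6/26.1/32.3%).
* **True exposure** is a latent recent-use Bernoulli per substance with
  logistic dependence on demographics.  Exposure-model intercepts were solved
  numerically on those margins so the marginal blood positivity is 7.4%
  (cannabis) and 2.6% (alcohol), the fused population-level estimates of the
  source study; the slopes encode the usual gradients (younger, male, less
  educated use more).
* **Blood vs oral tests.**  The study never states their joint distribution.
  Here the blood indicator *is* the latent use; the oral test is a second,
  noisy indicator with positive agreement `concordance` (default 0.95) and a
  propensity-scaled false-positive rate, so the oral marginal sits slightly
  below the blood marginal, matching the ordering in the source tables.  A
  symmetric flip construction was rejected: at a 2.6% marginal, flip noise
  alone would exceed the prevalence.
* **Self-report** is generated from the blood truth through a
  `misclassification_profile()`: sensitivity/specificity 0.62/0.94 for
  cannabis and 0.88/0.47 for alcohol, with a logit offset lowering
  sensitivity for the Black race group (-0.25 cannabis, -1.10 alcohol) —
  the dominant differential pattern in the source accuracy table.
* **Outcome** follows a logistic model on demographics and true blood
  positivity with the source study's fused odds ratios (cannabis 3.50,
  alcohol 18.53, male 2.94, Black 5.25, ...).  The intercept (-6.04) was
  solved for a 1% marginal case prevalence, reproducing the roughly 1:10
  case:control ratio of the real systems at the default sample sizes.
* **Design.**  Persons are spread uniformly over 10 strata x 8 PSUs; each
  survey samples 4 PSUs per stratum and then persons within PSUs at the
  fraction that hits the target size; weights are inverse inclusion
  probabilities.  The registry has no design variables until augmentation.
  PSU assignment is independent of outcome and exposure, so the design is
  non-informative; the design machinery is exercised structurally (weights,
  strata, PSU resampling), not through intra-cluster correlation.
* **The validation subpopulation** ("drivers") is selected by a logistic
  model on demographics (more male, more 21-34, more Black, more college),
  reproducing the covariate shift between the two surveys.  Crucially the
  *conditional* exposure model is shared — the identifying assumption of the
  fusion method.
* **Missingness** is missing-at-random with marginal rates taken from the
  missing counts of the source tables (e.g. 43% missing education and 65%
  missing blood cannabis in the registry, 55% missing blood tests in the
  validation survey), with a mild dependence on sex and age; the missingness
  intercept is solved so the marginal rate is hit exactly in expectation.
  Self-report and oral tests are *structurally* absent in the registry and
  biomarkers structurally absent in the control survey.

What passing tests on these data do **not** show: robustness to informative
cluster effects, to violations of conditional transportability (the driver
shift here is exactly the kind the method assumes away), or to
missing-not-at-random mechanisms.  Those are limitations of the method, not
of the implementation, and the generator deliberately satisfies the method's
assumptions so that estimator bias is attributable to the implementation.

## Harmonization

Validation-survey recency categories collapse to past-month use (past 24 h /
2 days / month are positive), any non-zero weekly drinking frequency is
positive, and concentrations dichotomize at 0.01 g/dL (blood) and 10 mg/dL
(oral fluid), thresholds inclusive.  Ages bin into 16-20 / 21-34 / 35-49 /
50-64 / 65+ with inclusive lower bounds.  Missing always maps to missing.
`add_registry_design_variables()` gives every registry row its own PSU, one
fresh stratum label, and weight 1, so registry rows enter the design-based
machinery as independent unit-weight observations.

## The chained-equations engine

`chained_impute()` cycles through the incomplete variables in ascending
missingness order, fitting one conditional model per variable on the
originally observed rows (predictors: all other demographic and exposure
variables at their current values) and drawing imputations from the fitted
conditional probability — Bernoulli draws, never rounded.  Chains are
initialized from observed within-source margins.  Three numerical choices
deserve explanation:

* **Source indicator and weights are excluded from the conditionals.**  For
  control-survey rows the biomarker is never observed, so a source main
  effect is unidentified; excluding it *is* the conditional-exchangeability
  assumption.  Weight scales are incomparable across systems;
  `include_weights = TRUE` adds within-source normalized log-weights for
  sensitivity analysis.
* **Firth bias reduction with intercept recalibration.**  Blood and oral
  tests of one substance agree almost always, so their conditional
  likelihoods are near-separated.  An unpenalized fit saturates
  (P(blood+|oral+) -> 1), which makes the concordant-positive state of the
  Gibbs chain absorbing and the imputed prevalence drift; a ridge strong
  enough to prevent that shrinks the coupling itself and biases the
  stationary distribution downward.  The Firth (Jeffreys-prior) adjustment
  keeps separated fits finite while barely shrinking identified
  coefficients; because Firth pulls rare-event fitted probabilities toward
  1/2, the intercept is then recalibrated by one-dimensional maximum
  likelihood with the linear predictor as offset (the FLIC correction).
  Demographic conditionals are well-behaved and use a lightly ridged fit.
* **Blocked draws for the blood/oral pairs.**  Even with well-calibrated
  conditionals, visiting the two members of a near-deterministic pair one at
  a time creates a sticky two-site chain whose stationary marginal amplifies
  small fitting errors.  Where *both* members are missing (the entire
  control survey) the pair is drawn jointly as a four-state categorical
  block conditional on everything else; rows with a single missing member
  fall back to the usual univariate conditional.  Jointly missing pairs are
  initialized concordantly.

`proper = TRUE` refits each conditional on a with-replacement resample of
its observed rows, a bootstrap analog of posterior draws (penalized and
forest learners lack tractable posteriors).  Inside `bmi_pipeline()` this is
forced off: the outer bootstrap already carries the parameter uncertainty,
which is precisely the bootstrap-then-impute construction.

Binary targets accept three learners — plain logistic, lasso logistic
(`glmnet`, penalty by 5-fold cross-validation inside each fit) and random
forest (`ranger`) — compared by `select_learner()` with stratified 10-fold
cross-validated AUC/sensitivity/specificity on validation rows with an
observed gold standard, ties broken by candidate order.  Multi-level
categorical targets (education, race, age) use one-vs-rest fits with
normalized probabilities as the learners' multinomial analog.  The package
default (and the choice in the tests and the acceptance script) is the plain
logistic learner: on the generator's 16-dummy predictor set the three
learners are near-indistinguishable in cross-validated AUC, and the
regression learners dominate the forest at these sample sizes, so the
cheapest stable learner is used where thousands of conditional fits are
needed.  `n_iterations` defaults to 10 sweeps; the imputed-mean traces
stabilize after 2-3 sweeps under the blocked design (the trace is stored on
every completed dataset, with a warning on non-stabilization), so the
bundled tests and the acceptance script run 3-5 sweeps.

## Estimation and variance

`fit_weighted_logistic()` solves the weight-multiplied logistic score
equations (pseudo-MLE) by iteratively reweighted least squares with
step-halving, in compiled code.  Reference levels are fixed (35-49, female,
White, HS graduate, test-negative) so synthetic odds ratios are directly
comparable with the source study's tables.  Zero-variance terms are dropped
with a warning; separation is flagged as non-convergence naming the worst
term, never silently penalized — a penalized replicate would contaminate
pooling.

`design_based_variance()` is the Taylor-linearization sandwich for a
stratified multistage design: weighted score contributions are totalled per
PSU; their between-PSU covariance within each stratum, with the
n_h/(n_h - 1) factor, forms the meat; the inverse weighted information the
bread.  With one record per PSU, one stratum and unit weights it reduces to
the textbook heteroscedasticity-consistent sandwich times n/(n - 1); a
single-PSU stratum is an error naming the stratum.

The four analysis models mirror the source study: model 1 is the BMI
pipeline on fused control + registry data; model 2 fits M fusion imputations
and pools by Rubin's rules with the design-based within-imputation variance;
model 3 is the listwise-deletion complete-case analysis of validation +
registry; model 4 multiply imputes the stacked validation + registry data
and pools by Rubin's rules.

## Resampling inference

`stratified_bootstrap()` redraws n_h PSUs with replacement within each
survey stratum (all records of a drawn PSU enter, with replicate-tagged PSU
labels; the Rao-Wu n_h - 1 variant with weight rescaling is available by
flag) and resamples registry rows individually at original size.  Duplicated
PSUs keep their weights: the bootstrap targets total variability rather than
design-consistent reweighting.

`bmi_pool()` implements the one-way ANOVA combination on the B x M grid:
the point estimate is the grand mean; with MSB the between-bootstrap and MSW
the within-bootstrap mean squares,

V = [(1 + 1/B) MSB - MSW] / M,

with Satterthwaite degrees of freedom

nu = V^2 / [ ((1+1/B) MSB/M)^2/(B-1) + (MSW/M)^2/(B(M-1)) ].

The combination can go negative in degenerate grids; it is then truncated at
the Monte-Carlo floor MSW/(BM) — the grand mean always carries at least its
own simulation variance — and flagged.  `rubin_pool()` implements the
classical rules (T = W + (1 + 1/M) B_var, df = (M-1)(1 + W/((1+1/M)B_var))^2)
with an infinite-df flag when the between-imputation variance is zero.
Per-replicate seeds derive from the master seed through a counter-based
recurrence, so any replicate is reproducible in isolation and the grid is
invariant to execution order.

## Problem sizes

The defaults simulate a population of 50,000 with 5,000-record surveys and
roughly 500 registry cases — about one tenth of the real systems, with the
same case:control ratio.  The bundled tests exercise the full pipeline at
this scale (bootstrap coverage of the generating cannabis log-OR over 10
replications at B = 50, M = 2) and the replicate bookkeeping at the study's
recommended B = 200, M = 2 on a ~700-row input; parameter-recovery oracles
use populations up to 200,000 where only a single logistic fit is involved.
These sizes are the package's choices for a thorough desk-scale validation;
all of them scale up through `sim_config()` without code changes.

## Known limitations

* The conditionals of the chained system are fitted independently and are
  only approximately compatible; the blocked pair draw removes the worst
  consequence, but no joint model is fitted.
* Design-based variance assumes at least two PSUs per stratum and no
  finite-population correction.
* The registry's structurally absent columns (self-report, oral tests) are
  never imputed from registry data alone; they are imputed only where some
  source observes them.
* MNAR mechanisms, record linkage, and informative cluster effects are out
  of scope.
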