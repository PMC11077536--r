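---
title: "Methods: emulating a three-arm second-line antidiabetic trial with a prescribing-preference instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a three-arm second-line antidiabetic trial with a prescribing-preference instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefiv)
```

## The problem

When people with type 2 diabetes need a second oral drug added to metformin,
prescribers in England choose mainly among sulfonylureas (SU), DPP-4
inhibitors and SGLT-2 inhibitors. No randomised trial compares all three
head-to-head, and in routine data the choice is confounded: patients started
on the newer class tend to be younger and healthier in ways the record does
not measure (diet, exercise, engagement with care). `prefiv` implements a
target-trial emulation of this comparison: explicit eligibility criteria and
time zero, intention-to-treat arms, protocolised measurement windows, and an
instrumental-variable analysis that uses regional variation in prescribing
preference to remove confounding by unmeasured prognosis.

The instrument is the *tendency to prescribe*: for each patient, the share
of eligible initiators in their commissioning group (CCG) prescribed each
class during the 12 months preceding that patient's own start date. Because
groups with similar case-mix differ widely and persistently in these shares,
patients with the same prognosis receive different drugs for reasons
unrelated to their outcomes — the substance of a valid instrument. Relevance
is testable (we require a cluster-robust first-stage F above 100);
independence is probed with balance diagnostics across instrument tertiles;
the exclusion restriction and monotonicity are assumptions and are
documented as such.

## The synthetic data-generating process

Real linked primary-care/hospital/death data of this kind are
access-restricted, so the package ships a generator
(`sim_config()`, `generate_cohort()`) whose output has the same shape as the
real linkage — five tables: patients, prescriptions, measurements, hospital
episodes, deaths — and a fully known truth, so every downstream stage is
testable end to end.

* **Structure.** ~100 CCGs nested in 7 regions; per-CCG preference triples
  drawn from a Dirichlet with concentration `(6.8, 9.1, 4.1)`, giving mean
  shares near the realistic 34/45/21 percent split with wide cross-group
  dispersion.
* **Assignment.** Multinomial logit per patient: linear predictor
  `instrument_strength * log(preference)` per arm, plus observed-covariate
  terms (older patients toward DPP-4, younger and more obese toward SGLT-2,
  higher baseline HbA1c toward SU), plus `confounding_unobserved * loading *
  U` with latent standard-normal `U` ("health consciousness": raises the
  odds of the newer classes and improves every outcome). Fixed arm
  intercepts (−0.1485 DPP-4, +0.7472 SGLT-2), solved once by fixed-point
  iteration, centre the marginal shares at the realistic split under the
  default configuration.
* **Continuous outcomes.** Follow-up value = baseline + drift + arm effect
  + regression-to-the-mean and age terms + `U` loading + Gaussian noise, at
  365 and 730 days. Default true effects (vs SU): HbA1c −1.0 (DPP-4) and
  −3.0 (SGLT-2) mmol/mol; BMI −0.8 / −1.6; SBP −0.3 / −2.1 mm Hg;
  eGFR 0 / +1.4 mL/min/1.73m².
* **Events.** Exponential times given covariates for heart failure
  admission, MI, stroke, CVD and non-CVD death, with a shared mean-1 gamma
  frailty per patient (`frailty_variance`, default 0.5) generated by inverse
  transform; default protective SGLT-2 hazard ratios for heart failure
  (0.46) and CVD death (0.8). Dropout is independent exponential
  deregistration. A ≥40 % eGFR decline is not a separate hazard: it emerges
  from the measurement trajectory, driven by a small CKD "progressor"
  subpopulation (5 % under SU/DPP-4, 3 % under SGLT-2) whose eGFR falls to
  65 %/45 % of baseline by one/two years — without it the decline endpoint
  would have essentially no events at these noise levels.
* **Missingness.** `impose_missingness()` deletes follow-up measurement rows
  at the observed real-world rates (≈34–48 % depending on measure and year),
  either MCAR or MAR with deletion log-odds linear in the baseline value of
  the same measure, intercept calibrated so the marginal rate is exact.
  Treatment, dates and event records are never deleted: the time-to-event
  record is treated as fully observed.

What the generator does *not* emulate: drug-level detail within classes,
code-list noise, visit-driven (outcome-dependent) measurement processes,
COVID-era disruption, or inter-CCG patient movement. Passing tests therefore
show the estimators are correct under the stated mechanism, not that any
real dataset satisfies the instrument assumptions.

## Cohort construction

`eligibility_rules()` / `build_cohort()` encode the protocol. Time zero is
the first-ever prescription of one of the three classes in 2015–2020.
Exclusions, applied in protocol order with a one-row-per-rule attrition log:
ambiguous index (two classes the same day), age under 18, no metformin in
the 60 days before, no metformin on or within 60 days after the index day,
pregnancy within 365 days, last recorded eGFR below 30 mL/min/1.73m², and
missing hospital linkage.

Decisions the protocol leaves open, resolved here and fixed:

* Patients with *no* eGFR on record are retained — exclusion requires a
  disqualifying value, not an absent one.
* A same-day measurement counts as baseline; all date arithmetic is in whole
  days with closed windows (HbA1c 180 days; blood pressure and eGFR 540;
  BMI latest-ever).
* Follow-up continuous values take the measurement closest to day 365/730
  within ±90 days; an exact tie is broken toward the *earlier* measurement,
  a deterministic and reproducible rule.
* Values at a timepoint the patient did not reach (death, deregistration or
  end of data first) are *undefined*, flagged `censored_by_y1`/`_y2`, and
  are neither analysed nor imputed.
* The ≥40 % decline endpoint triggers at the first post-index eGFR at or
  below 0.6 × baseline; patients with no baseline eGFR are excluded from
  decline endpoints only, with a logged count. MAKE is the earliest of
  decline or all-cause death; MACE the earliest of MI, stroke or CVD death
  (non-CVD death censors). A death dated on or before the index is treated
  as a data fault and the row is rejected with a log entry.

## The instrument

`compute_tendency()` computes, per patient, the class shares among
initiators of the same CCG with index dates in `[index − 365, index − 1]`.
The window ends the day before the patient's own index date, so the
instrument is leave-one-out by construction and cannot be mechanically
correlated with the patient's own treatment. Fewer than 5 contributing
initiators flags the instrument undefined (tiny-window proportions are
noise); undefined rows are dropped from IV analyses with a logged count.
Because the three shares sum to one, only `z_DPP4` and `z_SGLT2` enter any
model (SU is the reference throughout). Tendencies are computed from
study-eligible initiators, the literal reading of "eligible people".

`weak_instrument_test()` fits, per non-reference arm, the linear first-stage
regression of the arm indicator on the two shares plus all baseline
covariates, and reports the joint Wald F on the share coefficients with a
heteroscedasticity-consistent covariance clustered on region, against the
F > 100 relevance rule. `balance_diagnostics()` reports absolute
standardised mean differences of every covariate between top and bottom
*tertiles* of each arm's tendency (tertiles, not quintiles: stable with
~100 CCGs), with the conventional 0.1 reference line.

## Estimation

The main estimator is two-stage residual inclusion (2SRI), which returns
average treatment effects for the full population rather than a
complier-only contrast:

1. **First stage** (`fit_first_stage()`): one joint multinomial logit of arm
   on `(z_DPP4, z_SGLT2, covariates)` — a single system, not three pairwise
   models, so fitted probabilities sum to one and contrasts are coherent.
   The *generalised residual* is the multinomial score residual, indicator
   minus fitted probability, the natural choice for a logit first stage
   (it reduces to the familiar binary form). A linear-probability variant
   (`method = "linear"`) exists because residual inclusion with a linear
   first stage reproduces two-stage least squares exactly — an algebraic
   identity the test suite verifies against an independently coded IV
   estimator at tolerance 1e-8.
2. **Second stage**: for continuous outcomes, OLS of the
   baseline-to-follow-up change score on the two arm indicators, the two
   residuals and the covariates; for time-to-event outcomes, a Cox
   partial-likelihood fit with the same design plus an individual gamma
   frailty (Efron tie handling), the standard conjugate frailty choice.
   If the frailty variance is estimated at the boundary the model falls
   back to a plain Cox fit, and `theta = 0` requests that reduction
   directly. All three contrasts are read from one joint fit and are
   exactly transitive.

Per-fit standard errors of two-step estimators are inconsistent; they are
reported as diagnostics only, and headline inference comes from the
bootstrap (below).

Comparators mirror the usual sensitivity suite: `estimate_2sls()` (linear
IV benchmark), `estimate_naive()` (multivariable OLS/Cox assuming no
unmeasured confounding), `estimate_iptw()` (multinomial propensity weights,
non-stabilised or stabilised, with optional asymmetric quantile trimming of
the weights, sandwich variances) and `estimate_weighted_regression()` (the
doubly robust IPT-weighted outcome regression).
`select_covariates_pds()` implements post-double selection: LASSO of the
outcome on base + candidate expansions (squares and pairwise interactions of
the numeric covariates) and LASSO of treatment on the same dictionary, both
at the cross-validated one-standard-error penalty with a fixed fold seed;
the selected set is the union of candidate supports and the base covariates
are never penalised away.

## Missing data

`mice_pmm()` implements chained equations with predictive mean matching,
run *fully separately* within each stratum of arm × died/censored status.
Each sweep regresses a target on its predictor set over the observed rows
of the stratum, predicts the mean everywhere, and fills each missing entry
with the observed value of one of the 10 donors with nearest predicted
mean, drawn uniformly; the matching uses the least-squares fit directly
(no posterior draw), which keeps the donor pool reproducible and is the
reading of "predictive mean matching with 10 donors" adopted here.
Imputed values are therefore always members of the observed within-stratum
support — asserted on every run. Defaults: m = 5 imputations, 10 chained
sweeps, initial fill drawn from the stratum's observed marginal;
categorical targets match on predicted class-probability scores. Exact
predictor sets are configuration, not hard-coded:
`default_predictor_sets()` conditions each measure on the same measure at
the other timepoints, the other baselines, and age and sex, and
`congeniality_features()` aligns the imputation with the analysis — for
time-to-event analyses it adds the event indicator and the Nelson–Aalen
cumulative-hazard transform of follow-up time to every predictor set.

## Inference

`run_nested_bootstrap()` draws B bootstrap replicates stratified by
CCG × arm × died/censored status (stratum sizes are preserved exactly),
re-runs imputation (m per replicate) and the full first- and second-stage
estimation inside each replicate, pools each replicate's m estimates by
Rubin's first rule (the arithmetic mean, on the log scale for hazard
ratios), and reports point ± t(B−1, 0.975) × SD of the replicate
estimates. Choices made where the method description admits more than one
reading, each available as an option:

* the interval is centred on the Rubin-pooled estimate from the *original*
  data, not the bootstrap mean;
* "t-based" is read as the simple t-multiplier interval; a percentile
  option exists;
* the tendency shares are a fixed patient attribute looked up by id, while
  covariate selection and both model stages are re-estimated inside every
  replicate, so the interval reflects all estimation stages;
* failed replicates are excluded (never retried — retrying would bias
  toward easy resamples) and counted in `B_eff`;
* replicate b draws its RNG streams from the master seed and b, so any
  single replicate is independently reproducible.

## Problem sizes used by the test suite

The package's statistical guarantees are exercised at sizes chosen to make
the checks sharp but cheap, stated here as the package's own study design:

* parameter recovery: 100 datasets of n = 20,000 in 100 CCGs, strong
  instrument (`instrument_strength = 3`), `confounding_unobserved = 0.5`,
  complete outcomes, *event rates zero* — death depends on the latent
  confounder, so survival selection into the 1-year outcome sample would
  add a bias no IV estimator removes; setting event rates to zero isolates
  the confounding mechanism the estimator is built for (the survivor
  selection itself is visible in the full default configuration);
* relevance diagnostics: the first 100 recovery datasets (strong case) and
  40 null-instrument datasets of n = 4,000;
* imputation versus complete case: 60 datasets of n = 1,500 with 30 % MAR
  deletion of the 1-year HbA1c;
* bootstrap coverage: 60 simulated pipelines of n = 2,500 with B = 60,
  a reduced covariate set, and complete outcomes (so the imputation layer
  is exercised separately);
* exact identities (2SRI = 2SLS; frailty-at-zero = plain Cox; the
  hand-computed eligibility, outcome-window and tendency fixtures) at
  n = 500–2,000.

## Known limitations

2SRI with a nonlinear first stage is consistent under a control-function
assumption on the latent confounder, not fully nonparametrically; with a
strong instrument its residual bias is well inside the Monte Carlo margins
used here, but it is not exactly unbiased. The instrument diagnostics
cannot validate the exclusion restriction or monotonicity. Weight trimming
in IPTW truncates rather than deletes, which changes the estimand slightly
under extreme weights. The imputation model is linear per target;
interactions enter only through the predictor sets supplied. Bootstrap
intervals hold the tendency shares fixed, understating (slightly) the
sampling variability of the instrument itself.
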