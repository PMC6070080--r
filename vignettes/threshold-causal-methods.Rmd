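---
title: "Estimating treatment effects at an eligibility threshold: fuzzy regression discontinuity and IPW marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating treatment effects at an eligibility threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmsm)
```

## The setting

`rddmsm` implements two causal-inference pipelines for a common
epidemiological situation: a treatment is assigned by a threshold rule on a
continuously measured clinical marker, uptake of the assigned treatment is
imperfect, and the outcome is death observed in discrete time.  The
motivating example is antiretroviral therapy (ART) in an HIV care
programme where patients became treatment-eligible once their CD4 count
dropped below 200 cells/μL, treatment uptake jumped — but not from 0 to
1 — at that threshold, and mortality was recorded by population
surveillance.  Because sicker patients (lower CD4) are both more likely to
be treated and more likely to die, a naive comparison of treated with
untreated patients is confounded by indication and typically points the
wrong way.

The two pipelines answer subtly different questions under different
assumptions:

* **Fuzzy regression discontinuity (RDD)** exploits the threshold itself.
  Patients just below and just above 200 cells/μL are assumed
  exchangeable (the *continuity* assumption), so the jump in mortality at
  the threshold identifies the intention-to-treat (ITT) effect of
  *eligibility*, and instrumenting actual treatment with eligibility
  identifies the complier average causal effect (CACE) — the effect of
  treatment among patients whose initiation was moved by the rule.  No
  unmeasured-confounding assumption is needed, but the estimate is local
  to the threshold.
* **Inverse-probability-weighted marginal structural models (IPW MSM)**
  assume no unmeasured confounding given the measured baseline (and, for
  time-varying treatment, time-updated) covariates.  Reweighting each
  person-period by the inverse probability of the treatment actually
  received creates a pseudopopulation in which treatment is independent of
  the measured confounders; an unadjusted discrete-time hazard model in
  that pseudopopulation estimates a marginal effect for the whole cohort.

Because no individual-level data from such programmes are public, the
package ships a synthetic-cohort generator (`generate_cohort()`) that
reproduces the *structure* of these data with known ground truth, so both
pipelines are validated end-to-end by parameter recovery rather than
against irreproducible case-study numbers.

## The discrete-time hazard model

All survival models in the package are discrete-time hazard regressions on
a person-period table (`expand_person_periods()`): one row per subject per
month at risk, with the event indicator as outcome.  With the
complementary log-log link,

$$\Pr(Y_{it} = 1 \mid \text{at risk}) \;=\; 1 - \exp\{-\exp(\eta_{it})\},
\qquad \eta_{it} = \alpha(t) + \beta' x_{it},$$

coefficients are genuine log hazard ratios, invariant to the period
length; the logit link (giving discrete-time odds ratios) is offered
because published "hazard ratios" from discrete-time models are sometimes
odds ratios.  Smooth period effects $\alpha(t)$ enter as a natural cubic
spline in the period index with 3 degrees of freedom — a restricted cubic
spline with boundary and one interior knot — rather than one indicator per
period, for stability inside narrow CD4 bandwidths; with fewer than five
distinct periods the code falls back to period indicators.

## The synthetic cohort

`sim_config()` collects every generator knob.  The defaults describe the
study conditions the package is tested under:

* **Assignment variable.**  Baseline CD4 is drawn from a linearly
  decreasing density on [0, 350] cells/μL, solved in closed form so that
  the mass below 200 equals 62.0% (2,751/4,435, the eligible fraction of
  the motivating programme) while the density stays continuous at the
  threshold — the RDD's own continuity diagnostic
  (`density_continuity_check()`) must pass on clean data.  The implied
  stratum medians (≈95 and ≈271 cells/μL) approximate the programme's
  101 and 268.
* **Treatment assignment.**  Initiation in the first monthly period occurs
  with probability 0.75 below and 0.15 above the threshold (the fuzzy
  first stage); initial non-initiators start later with a constant
  per-period hazard of 0.03, emulating deferral to subsequent 6-monthly
  monitoring visits.  A single uniform draw per subject determines the
  potential initiation status on both sides, so compliance classes
  (always-taker / complier / never-taker) are well defined and
  monotonicity holds by construction — there are no defiers to exclude.
* **Mortality.**  The untreated monthly hazard is
  $\exp(-4.0 - 0.007\,\mathrm{CD4}_t)$; current ART multiplies the hazard
  by $e^{\beta}$ with $\beta = \log 0.5$ by default.  Intercept and slope
  were calibrated so a default cohort reproduces the motivating
  programme's printed incidence (about 4.9 deaths per 100 person-years
  overall; 6.6 among eligible, 2.5 among ineligible patients — the
  simulated values are 5.0, 6.7, 2.6).  The hazard is strictly decreasing
  in CD4, which is the confounding-by-indication mechanism.
* **Monitoring and censoring.**  Laboratory visits are scheduled every 6
  months, each missed with probability 0.2; the entry measurement always
  exists.  Disengagement from care (default 1% per month) stops lab visits
  and any later ART initiation, but deaths remain observed to the
  administrative end of follow-up — mortality ascertainment is by
  population surveillance, not clinic contact.  Knobs
  (`dropout_cd4_slope`, `dropout_art_multiplier`, `cd4_sd`) make
  disengagement respond to the last *measured* CD4 value and to treatment
  status, which is how informative censoring is switched on for the
  censoring-weight experiments; they are off (non-informative) by default.
  Disengagement responds to the measured rather than the latent count
  because that is what a clinic can act on — and it keeps the
  censoring-weight model correctly specifiable from observable data.
* **Covariates.**  Age, sex, education, distance to clinic and residence
  are drawn with realistic marginals (with ~10% missing residence, ~2%
  missing education) but are independent of treatment and outcome by
  default: the weight models must *handle* them, including their missing
  categories, while only CD4 actually confounds.  The 32 binary household assets follow a one-factor
  latent wealth model; the wealth index is the first principal component
  of the asset matrix, binned into quintiles by rank (so degenerate score
  distributions still bin deterministically), with ~10% of inventories
  missing.

Reproducibility is bit-for-bit: all randomness is drawn up front in a
fixed, documented order, so a `(config, seed)` pair identifies a cohort
exactly regardless of platform-level iteration details.

What the generator does **not** emulate: verbal-autopsy misclassification
of deaths, migration, clinic-level effects, calendar trends, or a
realistic joint distribution between socioeconomic covariates and
survival.  Passing recovery tests therefore demonstrates that the
estimators are correct *under their stated assumptions*, not that those
assumptions hold in any particular real cohort.

## Cohort preparation rules

* Eligibility is *strictly* below the threshold: a count of exactly 200
  is ineligible, following the rule "eligible once the count has dropped
  below 200".  Configurable.
* The baseline ("immediate") exposure of the time-invariant analyses is
  initiation within a 3-month grace period of entry.
* Bandwidth windows are inclusive on both endpoints; `150–250` keeps both
  150 and 250.
* The discrete period is 1 month by default — fine enough that
  discrete-hazard coefficients approximate continuous-time log hazard
  ratios, coarse enough for desk-scale Monte Carlo.  The time origin is
  the first CD4 measurement; entry is period 0.
* Lab-gap censoring (`apply_lab_gap_censoring()`) removes a subject's
  person-time from the first period starting 12 or more months after the
  last recorded measurement; events beyond that point are discarded and
  the last retained row is flagged.  It is idempotent, applies only to
  time-varying analyses, and person-time is conserved exactly (to 1e-9)
  through expansion and censoring.

## The RDD pipeline

`fit_rdd_itt()` regresses the per-period event indicator on the
eligibility indicator, separate linear CD4-gap terms above and below the
threshold, and period effects, within a bandwidth window.  Sensitivity
forms: a squared gap term below the threshold, or a natural cubic spline
in CD4 with an interior knot at 125 cells/μL and boundary knots at the
window edges; baseline age and sex can be added.  The exponentiated
eligibility coefficient is the ITT hazard ratio; intervals are Wald on the
coefficient scale.  Subjects exactly at the threshold count as
above-threshold (ineligible); subjects exactly at a window endpoint are
included.

`fit_first_stage()` estimates the jump at the threshold in the probability
of initiation within 6 months from side-specific linear probability fits —
the instrument-strength diagnostic matching the classic uptake figure
(`binned_summary()` provides the 10-cell/μL binned version of both the
uptake and mortality curves).

`fit_rdd_cace()` estimates the effect of treatment itself among compliers
by full maximum likelihood of a recursive bivariate probit: a probit
outcome equation containing current ART status, a probit treatment
equation containing the excluded eligibility instrument, and correlated
errors.  Implementation choices that matter:

* the bivariate normal CDF is a vectorized Gauss–Legendre quadrature of
  the Drezner–Wesolowsky identity, with the quadrature order raised as
  $|\rho| \to 1$ (12/32/64 nodes; cross-checked against an independent
  implementation to ~1e-8);
* the score is analytic, columns are scaled to unit standard deviation,
  and $\rho = \tanh\theta$ is estimated unconstrained (clamped to ±0.999);
  a short BFGS pass locates the basin and damped BHHH steps — Gauss–Newton
  on the outer product of scores, which approximates the information
  matrix — polish to a gradient norm scaled to the sample size; standard
  errors are the BHHH (outer-product) ones;
* duplicate person-period covariate patterns are collapsed with frequency
  weights before the ML pass (the likelihood is identical; the row count
  drops by roughly a factor of four);
* if the ML surface fails to converge, a two-stage residual-inclusion
  probit is used and tagged in the output;
* instrument strength is judged at the *subject* level (person-period
  rows of one subject are not independent draws of the uptake process);
  a subject-level jump within 1.96 standard errors of zero attaches a
  weak-instrument warning.

When treatment coincides with eligibility on every row — a sharp design —
the system degenerates and a single-equation probit is fitted, which makes
the CACE reproduce the ITT exactly (a required identity, tested to 1e-6).

**Probit-to-hazard-ratio conversion.**  The source analyses report the
instrumented-probit result as a hazard ratio without stating the mapping,
so a defensible choice had to be made: the package standardizes — it
averages the implied per-period event probabilities with and without
treatment over the observed covariate distribution and forms the
discrete-hazard ratio $\log(1-\bar p_1)/\log(1-\bar p_0)$.  On sharp
synthetic designs this conversion recovers the generating log hazard
ratio; evaluating instead at covariate means (the other obvious choice) is
visibly miscalibrated because the probit coefficient is dominated by the
high-risk end of the CD4 range.  The interval is obtained by transforming
the coefficient interval endpoints, an approximation flagged in the
output.

`wald_cace()` provides the classical IV sanity check: the ITT risk
difference divided by the first-stage jump.

## The IPW MSM pipeline

`fit_baseline_weights()` estimates stabilized weights for the
time-invariant exposure: denominator a logistic model of immediate
initiation on the baseline covariates — age, sex, baseline CD4 (entered
linearly *plus* the eligibility indicator, since assignment follows the
threshold rule on that count), education, wealth quintile, distance, and
residence, with missing values of categorical covariates as an explicit
category rather than dropped rows — numerator the marginal initiation
probability.  Only baseline CD4 is used (no time-updated values), matching
6-monthly monitoring practice.

`fit_timevarying_weights()` handles the time-varying exposure: pooled
logistic models of initiation among the not-yet-treated, the denominator
adding the most recent recorded CD4 carried forward between labs; because
treatment is absorbing ("remaining on ART"), post-initiation periods
contribute a factor of one, and per-row weights are cumulative products
(verified against a brute-force per-subject loop to 1e-12).

`fit_censoring_weights()` corrects for the 12-month lab-gap censoring with
inverse-probability-of-censoring weights.  Both its models condition on
treatment history (current ART status) and the baseline covariates; the
denominator adds current recorded CD4.  Conditioning on treatment history
is not optional: retention in care differs by treatment status, and
without ART in the censoring models the weights demonstrably fail to
remove censoring bias in the generator's informative-dropout scenario.

`fit_msm()` fits the weighted discrete-time hazard model: unadjusted on
the baseline exposure for the time-invariant MSM; on current ART status,
additionally conditioning on the numerator's baseline covariates (baseline
CD4 and eligibility), for the time-varying MSMs — the time-varying
estimate is therefore conditional on baseline covariates, as such models
are.  `fit_msm_interaction()` adds ART × years-since-entry and reports the
per-year multiplicative change in the hazard ratio.  All weighted fits use
quasi-likelihood with a subject-clustered sandwich variance: weights
induce within-subject dependence, and the source analyses do not state
their variance estimator, so the conservative standard choice is made.
Weight truncation is available (`truncation` percentiles in
`weight_model_spec()`) but off by default.  `weight_diagnostics()` reports
mean/sd/extremes and warns when the mean strays from 1 by more than 0.1 or
any weight exceeds 10.  Positivity is checked on the probability of the
*observed* status (a structural zero for a status nobody has — e.g. late
initiation switched off — is not a violation); fitted probabilities below
1e-6 raise an error.

## Validation design and problem sizes

The test suite validates both pipelines by parameter recovery at sizes
chosen to finish on a single desk CPU:

* **Sign reversal** (the qualitative fingerprint of confounding by
  indication): over 50 default cohorts of n = 2,000 with true HR 0.5, the
  unadjusted estimate is harmful on average while the weighted MSM is
  protective.
* **Recovery**: over 100 cohorts of n = 5,000 with a strong first stage
  (initiation probabilities 0.9/0.1, deferred initiation off so that
  immediate initiation coincides with ever-treatment and log 0.5 is the
  estimand of both estimators), the mean log hazard ratio of the
  baseline-weight MSM and of the CACE lie within ±0.1 of log 0.5.
  Follow-up is 36 monthly periods here: the marginal hazard ratio of an
  MSM coincides with the conditional one only while risk-set depletion is
  modest (hazard ratios are noncollapsible), and three years keeps that
  gap well inside the tolerance while providing enough events for the
  instrumented probit.  Measured at these sizes the MSM mean is ≈ −0.66
  and the CACE mean ≈ −0.74 against a truth of −0.693.
* **Null calibration**: with true HR 1, over 200 cohorts of n = 2,000,
  the 95% intervals of the ITT (window 150–250) and the MSM cover 1
  between 90% and 99% of the time.
* **Oracles**: cumulative weights against a per-subject loop (1e-12), GLM
  coefficients against direct likelihood maximization on a 30-row fixture
  (1e-3), person-time conservation (1e-9), the bivariate normal CDF
  against an independent implementation (1e-7), and the analytic score
  against numerical differentiation.

`scripts/acceptance.R` re-runs scaled versions of these experiments from
scratch against the installed package and writes the resulting numbers as
JSON.

## Known limitations

* The CACE interval transformation ignores uncertainty in the nuisance
  coefficients of the standardization; the point conversion is validated,
  the interval is approximate.
* OPG (BHHH) standard errors for the bivariate probit treat person-period
  rows as independent; a subject-clustered version would be wider.  The
  ITT's model-based intervals are correct under the generator (conditional
  independence given covariates) but are not cluster-robust either.
* The time-varying weight models assume the recorded-CD4 history captures
  the confounding and censoring mechanisms; the generator's
  informative-dropout scenario is built to satisfy this (disengagement
  responds to measured CD4), so these experiments do not probe
  misspecified weight models.
* No data-driven bandwidth selection and no kernel weighting within the
  window: the three fixed windows of the motivating design are the
  supported sensitivity axis.
* The exact covariate sets of the source study's time-varying treatment
  and censoring models are described only in its supplement; the
  formulations here are the standard reconstruction and are documented as
  such.
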