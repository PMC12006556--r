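---
title: "Methods: regression-based cost-utility analysis of a two-arm sampling trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based cost-utility analysis of a two-arm sampling trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcua)
```

This vignette is the package's account of its statistical machinery: the
models, the standardisation, the missing-data treatment, the decision layer,
what the synthetic generator does and does not emulate, and the numerical
and design choices a maintainer would want to know about.

## The estimand and the pipeline

The package targets the within-trial cost-utility contrast between two
wound-sampling policies (tissue versus swab) for infected diabetic foot
ulcers: expected cumulative NHS/PSS cost and expected QALYs per patient at a
horizon of 26, 52 or 104 weeks, standardised over the trial population, and
the derived decision statistics (ICER with dominance classification, INMB
$\lambda\Delta Q - \Delta C$, INHB $\Delta Q - \Delta C/\lambda$ at
$\lambda$ = £20,000 and £30,000 per QALY, CEAC over £0–£50,000). The
incremental sign convention is fixed throughout: tissue minus swab.

Randomised arms can still be imbalanced at baseline — in the motivating
setting one arm was on average six years older — so raw arm means are
confounded with prognosis. The pipeline therefore estimates everything
through regressions on a common explanatory set (arm, mean-adjusted age,
sex, number of ulcers, ulcer area, ulcer duration) and marginalises by
corrected group prognosis (CGP): each patient is predicted under both
counterfactual arms with their own covariates, and predictions are averaged
over the full population. For purely linear components CGP collapses to the
prediction at the covariate means (tested to 1e-8); for the nonlinear
survival, ordinal and logistic components it does not, which is why the
standardisation is needed.

## The five regressions

All five models share one patient-level design matrix (asserted at fit
time). Age is centred at the sample mean, and the centring constant is
stored with each fit so counterfactual predictions reuse it.

* **Survival**: lognormal accelerated-failure-time model,
  $S(t \mid x) = 1 - \Phi\big((\log t - x\beta)/\sigma\big)$, fitted by
  maximum likelihood with right censoring via `survival::survreg`.
  `select_survival_family()` fits exponential, Weibull, lognormal and
  log-logistic alternatives and returns the AIC minimiser (BIC disagreement
  is reported, not silently resolved). The variance–covariance matrix keeps
  `survreg`'s native log-scale parameterisation so PSA draws of $\sigma$
  stay positive.
* **Utility and other NHS cost**: linear mixed models (REML, `lme4::lmer`)
  with a patient random intercept. Visit week enters as a categorical main
  effect interacting with arm, the minimal structure under which per-week
  arm contrasts exist. Empirical-Bayes random-intercept predictions are
  exported and carried into counterfactual predictions (the patient keeps
  their own random effect under either arm). If only one visit week is
  observed the categorical time structure is dropped; with one observation
  per patient the variance components are not separately identified and the
  fit degrades to the boundary rather than failing.
* **Hospitalisation**: proportional-odds logistic regression
  (`MASS::polr`) of the per-period worst admission category on the ordered
  scale none < other < minor-amputation-or-revascularisation <
  major-amputation. Categories unobserved in a dataset are merged upward
  into the next more severe observed category, with a loud warning. When
  only two categories remain the proportional-odds model *is* a logistic
  regression; the package fits it as such and re-expresses the result on
  the threshold parameterisation so downstream code sees one interface.
* **Antibiotic prescription**: plain logistic regression of
  any-prescription-in-period. A random-intercept logit is deliberately not
  used: at trial-scale sample sizes such models routinely fail to converge,
  and the fixed-effects fallback is the analysis this package implements.
  Perfect separation is detected and reported with the offending covariate.

Hospitalisation and antibiotic models are fitted per inter-visit period
(0–4, 4–12, …, 52–104 weeks) with no period term: the estimand is the
probability of a costed event occurring in a period. Periods enter only
while the patient is alive and under follow-up.

## From models to QALYs and costs

**QALYs.** Conditional utility (predicted at visit weeks, linearly
interpolated between them) is multiplied by the predicted survival curve and
integrated: trapezoidal quadrature on a 0.1-week grid, divided by 52
(1 year = 52 weeks exactly, so the week-104 horizon is 2.0 years). The
0.1-week grid keeps the trapezoid within 1e-4 of dense-grid quadrature
(tested against a 0.001-week oracle). Utility after death contributes
nothing via the $S(t)$ weighting; there is no separate death disutility.

**Event costs.** Per period: ordinal category probabilities times expected
category cost, prescription probability times expected course cost, and the
predicted 4-week-recall other cost scaled by (period length)/4. Expected
category and course costs default to the mean observed cost of events in
each category (falling back to unit-cost-table constants — episode cost at
average length of stay, plus rehabilitation for amputations, the midpoint of
minor amputation and revascularisation for the merged category — when a
category has no observed events). Period contributions are weighted by
survival at period start, so the dead are not charged; the weighting is
switchable (`cgp_options(survival_weighting = FALSE)`) because attaching
costs to deaths mid-period is a modelling choice, not a fact. Sampling costs
(£12 swab, £20 tissue) are charged per sampling occasion — one baseline
occasion plus a configurable expected number of follow-up occasions
(default 1) — and reported inside the "other" component.

**Discounting** is the one-factor second-year adjustment: amounts accruing
after week 52 are divided by 1.035, applied segment-wise in the QALY
integral so the year boundary splits exactly (the identity
"discounted two-year total = year one + year two / 1.035" holds to 1e-10).
A continuous-time discount would be over-engineering for a two-year horizon.

## Missing data

Self-reported streams (EQ-5D and the contact questionnaire, which share an
instrument and therefore share a missingness indicator) are handled by
available-case analysis or by multiple imputation; researcher-collected
streams (deaths, admissions, antibiotics) are complete by design and are
never imputed. Visits after death are structurally undefined — not missing
— and are excluded from both fitting and imputation.

The imputer is fully conditional specification on the analysis scale
(utilities and window costs, not 3L profiles): each variable is imputed by a
Bayesian linear regression draw (scaled inverse-chi-squared residual
variance, normal coefficient draw, predictive noise), in a fixed sweep order
(utility columns by week, then cost columns by week), with independent
chains per imputation and a burn-in of sweeps before each saved dataset.
Because death truncates follow-up, outcome columns at later weeks are
undefined for part of the sample; each column's predictor set is therefore
baseline covariates plus outcomes at the same or earlier weeks, which is
defined for every eligible row. A light ridge (1e-5) stabilises nearly
collinear sweeps at small n. Observed values are never altered (tested).

"100 iterations sampled" in this literature is ambiguous between 100
imputations and 100 chained sweeps; the package reads it as m = 100 imputed
datasets (default `mi_config(n_imputations = 100, burnin = 10)`), and both
knobs are exposed. Tests and the bundled analyses use m = 20 for speed.
Deterministic MI results are Rubin means across imputations; `pool_rubin()`
implements the standard total-variance rule
$T = \bar W + (1 + 1/m)B$ with the large-sample MI degrees of freedom. For
MI + PSA, models are refit per imputed dataset and PSA draws are allocated
round-robin across imputations, so parameter and imputation uncertainty
propagate together.

## Probabilistic sensitivity analysis

Each model's full parameter vector is drawn from a multivariate normal at
its estimate and variance–covariance matrix: within-model correlation is
preserved; draws across models are independent, because no joint covariance
across separately fitted models is estimable — a documented limitation.
The AFT scale is drawn on the log scale; proportional-odds threshold draws
that break monotonicity (rare) are redrawn. Empirical-Bayes random
intercepts are held at their point predictions across draws: their
conditional uncertainty is not available from separately serialised fits,
so PSA understates that (small) component. With all covariance matrices
zeroed, every draw reproduces the deterministic result exactly (tested).
The CEAC uses the strict rule INMB > 0 (ties count as not cost-effective),
and its λ → 0 end point is evaluated as the limit "fraction of draws with
ΔC < 0".

## The synthetic trial generator

No patient-level data from trials of this kind are publicly deposited, so
the generator is first-class, tested code that defines the study conditions
the package is exercised under:

* **Design**: 75 + 74 patients, recruitment uniform over a 155-week window,
  administrative stop at calendar week 207 (so every patient completes 52
  weeks but only those recruited in roughly the first two-thirds of the
  window can reach week 104), visits at 0/4/12/26/39/52/104 weeks.
* **Baseline**: age truncated-normal with arm-specific means/SDs 65.7
  (11.39) and 59.7 (12.98) — reproducing the age imbalance — sex Bernoulli
  (86.7%/78.4% male), ulcer area and duration lognormal matched to
  arm-specific medians and IQRs, ulcer count 1 + Poisson(0.33).
* **Outcomes** use exactly the analysis model families, so fitting is
  well-specified: death weeks from a lognormal AFT (intercept 5.22, arm
  effect +0.43, σ = 0.98, solved analytically from arm-level survival
  anchors of 0.90/0.72 and 0.96/0.85 at weeks 52/104); latent utilities
  from a linear mixed model whose week and arm-by-week effects equal the
  published arm-mean utility trajectory, with patient-intercept and residual
  SDs of 0.25 each (plausible for EQ-5D panels; the published per-visit
  standard errors imply total SDs of roughly 0.3–0.45), mapped to the
  EQ-5D-3L profile with the nearest tariff score (ties to the
  lexicographically smallest profile) so scoring round-trips; per-period
  hospitalisation categories from a proportional-odds model (baseline
  70/20/7/3% split, arm effect 0.20); antibiotic prescription from a
  logistic model (intercept logit(0.45), arm log-odds 0.602, the published
  antibiotic arm effect); contact counts Poisson with arm rate ratio
  exp(0.22).
* **Missingness**: administrative censoring removes any visit falling after
  the stop week; on top, per-visit MAR nonresponse with logit rates solved
  analytically from the published attrition margins (5.4%, 19%, 33.8%,
  43.8%, 57.9%, 54.8% and — among administratively reachable survivors —
  87.5% at week 104, which reproduces the ~68–76% overall week-104 missing
  fraction), with small dependencies on age and the previous utility so MAR
  is literally true in the generator.

What the generator does *not* emulate: wound-healing and microbiology
outcomes, intermittent "return after dropout" patterns beyond what
independent per-visit nonresponse produces, multiple prescriptions per
period, free-text adverse-event coding, and any association between
hospitalisation and subsequent utility beyond what the shared covariates
induce. Passing tests therefore demonstrate the *pipeline's* correctness
under a faithful but idealised data-generating process, not the clinical
conclusions of any real trial; in particular the generator is calibrated to
raw arm-level margins, so its regression-corrected incremental QALY need not
match published corrected results in sign or size.

## Numerical choices and degenerate inputs

* Optimiser settings: `survreg` rel. tolerance 1e-10 (max 500 iterations),
  `polr` reltol 1e-10, `glm` epsilon 1e-10; non-convergence surfaces as an
  error or warning, never silently.
* Variance–covariance matrices are checked for symmetry and positive
  semi-definiteness (tolerance 1e-8) at fit time and before PSA.
* Overlap resolution for same-dated admissions ("same dates" = identical
  start/end week pair, the narrowest reading) is order-invariant; equal-cost
  ties break by category name.
* Excess bed days are `max(0, observed − average length of stay)`; stays
  shorter than the costed average earn no rebate.
* Missing prescription duration/frequency fall back to configured defaults
  (7 days, minimum dosing), mirroring prescribing-guideline assumptions.
* EQ-5D profiles with any missing dimension are treated as missing (no
  partial scoring); utilities below zero are legitimate states worse than
  death.
* Horizons must lie on the visit schedule; utilities are never extrapolated
  beyond the last visit week.
* Degenerate cases covered by tests: zero-variance covariate distributions,
  σ → 0 survival (step function at the median), zero random-effect
  variance (mixed model collapses to OLS on balanced data), single
  observation per patient, two-category ordinal outcomes, zero event
  probabilities, zero PSA covariance, complete data through the MI path.

## Problem sizes used in the bundled checks

The test suite runs parameter-recovery studies at 200 replicates of n = 500
per model family (≥ 90% empirical coverage of 95% intervals), an MCAR
MI-versus-ACA comparison with fresh data per replicate (200 replicates,
m = 20), and an end-to-end synthetic pipeline at the trial's own size
(149 patients, m = 20, 200 PSA draws) whose incremental estimates are
checked against a 1,500-patient complete-data reference run of the same
generator. These sizes were chosen as the smallest at which the checked
properties are statistically sharp.

## Known limitations

* Across-model parameter draws in PSA are independent; any real correlation
  between, say, survival and utility parameters is not propagated.
* Random-effect uncertainty is excluded from PSA (point predictions only).
* The other-cost extrapolation treats each 4-week recall window as
  representative of its whole inter-visit interval — the standard
  assumption for sparse recall instruments, and exactly as strong here.
* Imputation on the utility scale can produce values outside the tariff
  range; they are analysed as-is (the analysis models are linear and
  unconstrained, so this is consistent, but profile-level imputation would
  be the stricter alternative and is out of scope).
* The expected antibiotic course cost enters as a single scalar per
  dataset; heterogeneity of course costs within a period is averaged over.
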