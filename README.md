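# trialcua

Within-trial cost-utility analysis for two-arm randomised trials with
repeated EQ-5D-3L measurement and continuously recorded resource use, in the
setting of wound-sampling policies (swab versus tissue sampling) for infected
diabetic foot ulcers, from the UK NHS/PSS perspective.

## What it does

Trials of this kind ask whether the more invasive, more informative sampling
policy is worth its extra cost. `trialcua` implements the full
regression-based pipeline from patient-level trial tables to decision
statistics:

1. **EQ-5D-3L scoring.** Five-dimension profiles are valued with the standard
   UK general-population time-trade-off tariff: for a profile
   $p = (p_1,\dots,p_5)$,
   $u(p) = 1 - c\,[\exists\, p_d > 1] - \sum_d \delta_{d,p_d} - n_3\,[\exists\, p_d = 3]$,
   giving $u \in [-0.594, 1]$.
2. **Costing.** Admissions are priced as HRG episode cost plus
   excess-bed-day cost for days beyond the costed average stay (plus a
   post-amputation rehabilitation cost); same-dated duplicate admissions keep
   only the most expensive event; antibiotic courses are priced from a
   BNF-style unit-price list; 4-week-recall healthcare contacts are costed
   from unit costs and extrapolated over the interval since the previous
   visit (all unit costs at 2021/22 prices, bundled as editable YAML).
3. **Five regressions on one covariate set** (arm, mean-adjusted age, sex,
   number of ulcers, ulcer area, ulcer duration): lognormal
   accelerated-failure-time survival
   $S(t\mid x) = 1 - \Phi\!\big((\log t - x\beta)/\sigma\big)$,
   linear mixed models (patient random intercept, categorical visit week
   interacting with arm) for utility and other NHS cost, proportional-odds
   hospitalisation category per inter-visit period, and logistic antibiotic
   prescription per period.
4. **Corrected group prognosis (CGP).** Every patient is predicted under
   *both* arms with their own covariates and empirical-Bayes random effect;
   QALYs are the area under $S(t)\,u(t)$ (utilities interpolated between
   visits, divided by 52 weeks/year), event costs are probability times
   expected event cost per period, weighted by survival at period start;
   averages over the population give standardised per-arm results and the
   incremental contrast (tissue − swab).
5. **Missing data.** Available-case analysis, or multiple imputation by
   fully conditional specification on the utility/window-cost scale with
   Bayesian linear draws, plus Rubin pooling.
6. **Decision layer.** One-factor 3.5% discounting of second-year accruals,
   ICER with dominance classification, INMB $= \lambda\Delta Q - \Delta C$
   and INHB $= \Delta Q - \Delta C/\lambda$, probabilistic sensitivity
   analysis by multivariate-normal parameter draws, CEAC and
   cost-effectiveness-plane tables.
7. **Synthetic trial generator.** Because patient-level trial data of this
   kind are not publicly deposited, `simulate_trial()` generates two-arm
   datasets with the same structure (staggered recruitment, administrative
   stop, the 0/4/12/26/39/52/104-week visit schedule, calibrated attrition),
   so the entire pipeline is testable end to end.

## Worked example

```r
library(trialcua)

dat <- simulate_trial(trial_config(seed = 42))   # 75 + 74 patients
res <- cua(dat, horizon = 52, missing = "ACA", method = "PSA",
           n_draws = 100, seed = 3)
res
```

```
Within-trial cost-utility analysis (ACA, PSA) at week 52
    arm  qaly antibiotics hospitalisation    other    total
   swab 0.450     211.730        7198.888 3402.136 10876.37
 tissue 0.516     290.636        9650.929 4631.417 14684.56
Incremental (tissue - swab): dQALY = 0.0653, dCost = £3808.19
  lambda £20,000: INMB = £-2501, INHB = -0.125 QALYs
  lambda £30,000: INMB = £-1848, INHB = -0.062 QALYs
ICER: £58287 per QALY
```

Reading the output: per-arm expected costs are split into antibiotics,
hospitalisation and "other" (sampling, healthcare-professional contacts and
non-admitted care); the incremental row is tissue minus swab; negative INMB
at both willingness-to-pay thresholds says tissue sampling should not be
adopted at those thresholds in this simulated dataset. `plot(res)` draws the
cost-effectiveness plane from the PSA draws; `run_pipeline(run_config())`
writes the full report bundle (per-component tables, decision summary, CEAC
and plane CSVs, reproducibility manifest) for every requested combination of
horizon, missing-data mode and evaluation mode.

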