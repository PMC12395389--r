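# strokeRK

Validation tooling for three-level stroke risk stratification in community
screening cohorts, written for epidemiologists and biostatisticians who
work with the Chinese "8+2" stroke screening programme or with
Rothman-Keller-style health risk appraisal more generally.

Screening programmes classify residents aged 40+ as low, medium or high
stroke risk from eight binary factors — hypertension, heart disease,
smoking, dyslipidemia, diabetes, physical inactivity, overweight, family
history of stroke — with a blunt counting rule (≥ 3 factors ⇒ high; fewer
plus chronic-disease history ⇒ medium; else low). This package implements
that rule and two weighted alternatives, and everything needed to compare
them:

* **Rothman-Keller model** — per factor, a baseline morbidity ratio
  ρ = 1 − PAR% scores the unexposed stratum and S = ρ × OR the exposed
  stratum; per participant the scores combine as
  Q = (Σ<sub>S≥1</sub> S<sub>i</sub> − (k − 1)) × Π<sub>S<1</sub> S<sub>j</sub>,
  and individual risk = incidence × Q, a relative risk level against the
  population average.
* **Logistic model** — ln(P/(1−P)) = α + Σ β<sub>i</sub>X<sub>i</sub>,
  fitted in-package by Newton/IRLS with Wald intervals and explicit
  separation/convergence diagnostics.
* **Monte-Carlo thresholds** — 100,000 Bernoulli exposure profiles at
  literature prevalences, scored and sorted; category cut points are the
  score values at configurable ranks (replication defaults 25844/77778
  logistic, 25426/64553 Rothman-Keller).
* **Evaluation suite** — Mann-Whitney/midrank AUC with DeLong variance and
  paired DeLong Z tests, sensitivity/specificity under both binarization
  rules, and three-category net reclassification improvement (NRI) with
  event/non-event decomposition.
* **Synthetic cohort generator** — seeded Bernoulli exposures, logistic
  outcomes with a root-found intercept calibrated to a target incidence,
  optional MCAR missingness; makes every stage testable end to end.

A packaged parameter table (`stroke_panel()`) carries the eight factors'
literature prevalences, odds ratios, logistic coefficients and PAR%
values, with the derived ρ and S columns.

## Worked example

```r
library(strokeRK)

panel <- stroke_panel()           # packaged 8-factor parameter table
coh   <- generate_cohort(n = 11692, seed = 2026)
mean(coh$outcome)
#> [1] 0.0678                      # 10-year incidence near the 6.6% target

thr <- derive_thresholds("rk", panel, sim_n = 100000, seed = 2026)
thr
#> Risk thresholds [rothman_keller]: low/medium 0.0074831171 (rank 25426),
#>   medium/high 0.02222708 (rank 64553); sim_n = 100000

cats_rule <- classify_8plus2(coh)                     # "8+2" counting rule
cats_rk   <- categorize(predict_rk(panel, coh), thr)  # weighted model

roc_auc(predict_rk(panel, coh), coh$outcome)
#> AUC = 0.670 (95% CI 0.651-0.688), DeLong variance 9.13e-05

nri(reclassification_table(cats_rule, cats_rk, coh$outcome))
#> NRI: events -0.131, non-events +0.286, absolute +0.155 (Z = 6.883, p = 5.88e-12)
```

Read: on a synthetic cohort whose outcomes truly follow the weighted
logistic mechanism, the Rothman-Keller score discriminates (AUC 0.67) and
its absolute NRI against the counting rule is positive — here the gain
comes from moving non-events out of the elevated categories (+0.286) at
some cost among events (−0.131). `run_pipeline(pipeline_config(...))`
chains all of the above (three models, pairwise DeLong comparisons, both
sensitivity/specificity rules, NRI vs the rule-based baseline) and writes
every artifact plus a JSON provenance record.

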