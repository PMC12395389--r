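---
title: "Methods: three-level stroke risk stratification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level stroke risk stratification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeRK)
```

## The problem

Community stroke-screening programmes in China classify residents aged 40+
into low, medium and high risk with the "8+2" scorecard: eight binary risk
factors (hypertension, heart disease, smoking, dyslipidemia, diabetes,
physical inactivity, overweight, family history of stroke) plus two history
items (TIA and prior stroke, which here are cohort exclusion criteria rather
than counted factors). The rule is blunt — every factor counts equally — so
the natural question is whether weighting the factors helps. This package
implements the rule, two weighted alternatives, the Monte-Carlo procedure
that places their category cut points, and the statistics used to compare
them, together with a synthetic cohort generator so that the whole pipeline
is testable without patient data.

## The three models

**Rule-based ("8+2").** High risk if 3 or more of the eight factors are
present; otherwise medium risk if there is any chronic-disease history
(hypertension, diabetes, heart disease); otherwise low. The printed rules
overlap at exactly 3 factors ("3 or more" high, "3 or less" medium); we give
high risk precedence, which matches the screening programme's intent of
sensitive high-risk capture. For ROC analysis the three levels enter as an
ordinal 0/1/2 score — the only reading under which a three-level rule has a
well-defined AUC.

**Logistic.** The standard model
$\ln\frac{P}{1-P} = \alpha + \sum_i \beta_i X_i$ over the eight binary
factors. `fit_logistic()` maximises the likelihood by Newton/IRLS iterated
to a score norm below $10^{-8}$; quasi-separation and non-convergence are
hard errors, never silent results. The fitter is deliberately implemented in
the package so the whole acceptance surface is self-contained; it is
cross-checked in the tests against `stats::glm` (agreement to $10^{-6}$ on
identical data) and against the closed-form cross-product odds ratio on
single-factor 2x2 cohorts.

**Rothman-Keller.** Each factor contributes a baseline morbidity ratio
$\rho_i = 1 - \mathrm{PAR}_i$ (the share of incidence *not* attributable to
the factor) when unexposed, and $S_i = \rho_i \times OR_i$ when exposed.
PAR% is a literature input in the packaged panel; Levin's formula
$P(OR-1)/(P(OR-1)+1)$ is available as an explicit opt-in fallback
(`par_fallback = TRUE`) but does **not** reproduce the packaged PAR column —
those values come from external cohort literature, and we take them as
given. (The alternative expression $\rho = 1/\sum OR_i P_i$ that appears in
the health-risk-appraisal literature does not reproduce the packaged
$\rho$ column either; $1 - \mathrm{PAR}$ does, exactly, so that is the
definition used.)

Per-participant scores combine by the standard synthesis: elevated scores
($S \ge 1$) add, protective scores ($S < 1$) multiply,

$$Q = \Big(\sum_{S_i \ge 1} S_i - (k-1)\Big) \times \prod_{S_j < 1} S_j,$$

with either term defaulting to 1 when its set is empty, so an all-neutral
panel gives $Q = 1$. Individual risk is $\text{incidence} \times Q$ — a
relative quantity measured against the population average, not a calibrated
probability. The incidence multiplier defaults to 0.066, the screening
cohort's observed 10-year incidence; no external source specifies this
multiplier, so it is configurable (`stroke_panel(incidence = )`).

A consequence worth noting: because dyslipidemia ($OR = 0.94$) and smoking
($OR = 0.88$) carry protective odds ratios in the packaged panel, the
minimum-risk exposure profile is exposed to *exactly those two* factors
(risk 0.00494), not the all-unexposed profile (0.00598), and the
maximum-risk profile is exposed to the six harmful factors but not those
two (0.0614), not the all-exposed profile (0.0508). The exhaustive
`enumerate_profiles()` table makes such facts checkable by inspection and
serves as the exact oracle for the simulation.

## Threshold derivation

Cut points for the two continuous models come from a Monte-Carlo population:
`sim_n` exposure profiles (100,000 by default, matching the reference
procedure) drawn as independent Bernoulli variables at the literature
prevalences, scored without outcomes, sorted ascending; the two thresholds
are the score values at fixed ranks. The selection rule behind the reference
ranks is unrecorded, so the ranks are configuration, shipped with the
observed replication defaults 25844/77778 (logistic) and 25426/64553
(Rothman-Keller). The reference node *scores* themselves depend on an
unrecorded seed and an unpublished logistic intercept and are not
reproducible; only the procedure and rank semantics are.

`categorize()` uses half-open intervals with boundaries belonging to the
upper category (value `>= t` is the upper class). One subtlety follows from
taking thresholds *at* the ranks: on a tie-free sample the node elements
themselves land in the upper category, so categorising the simulation sample
by its own thresholds yields groups of sizes $(r_1 - 1,\; r_2 - r_1,\;
n - r_2 + 1)$, and with eight binary factors both models take at most
$2^8 = 256$ distinct values, so heavy ties make exactly rank-sized groups
unattainable in general. Both conventions (value-at-rank, boundary-up) are
fixed and documented for reproducibility.

## The synthetic cohort generator

`generate_cohort()` emulates the screening cohort: `n` participants
(11,692 by default), independent Bernoulli exposures at the panel
prevalences, outcomes drawn from the logistic model with the panel's
coefficients, and the intercept calibrated by monotone root-finding so the
expected incidence hits a target (0.066 default) within $10^{-6}$.
Chronic-history flags default to the corresponding exposure columns, as the
screening instrument treats them equivalently. Optional missingness is
injected completely at random per factor (the study cohort lacked lipid
information for 2556 of 11,692 participants; the generator reproduces such
counts within binomial noise), and outcomes are never masked. All draws are
substreams of one master seed, so a rerun is bit-identical.

Because the generator's truth *is* the logistic form the analysis fits,
parameter recovery is a well-posed test; and because exposures are
independent (as in the reference simulation procedure), passing tests say
nothing about real-data features the generator does not emulate:
exposure correlation, confounding, age/sex/district structure, informative
missingness, or censoring over the 10-year follow-up. Multiple imputation
of injected missingness is deliberately out of scope; complete data are
required downstream.

## Model comparison

AUC is the Mann-Whitney statistic with midrank ties; its variance and the
paired two-model Z test use DeLong's structural components (delegated to
the pROC package; the test suite re-derives both from first principles as
independent oracles, and by brute-force all-pairs enumeration for the AUC).
Identical or rank-equivalent score vectors are reported as $Z = 0$, $p = 1$
rather than 0/0. Confidence intervals are Wald on the DeLong variance,
truncated to $[0, 1]$.

Sensitivity/specificity of a three-level classification needs a
binarization rule; none is canonical, so both are computed, with
"medium-or-high = screen positive" as the default (any elevated category
triggers follow-up in the screening programme) and "high-only" as the
alternative.

Categorical NRI is computed from the paired 3x3 reclassification tables,
per event stratum: $(\text{up} - \text{down})/n$ among events,
$(\text{down} - \text{up})/n$ among non-events, absolute NRI their sum
(range $[-2, 2]$), with the usual asymptotic Z using per-stratum variance
$(\text{up} + \text{down})/n^2$. Improvement for an event means moving to a
higher category; for a non-event, lower. All tests are two-sided at
$\alpha = 0.05$.

## The pipeline

`run_pipeline()` chains generate → fit → derive thresholds → score all
three models → evaluate, writing every artifact plus a JSON provenance
record (config, seeds, fixture columns), and is bit-identical under a fixed
master seed. The rule-based baseline is always computed from raw exposures
by its counting rule, never from thresholds. The exported functions and
file round-trip helpers are the package's interface; no shell wrapper is
shipped.

## Numerical choices and problem sizes

* Panel comparisons against the printed parameter table use tolerance
  5e-4 (its 3-decimal precision).
* Intercept calibration: `uniroot` on $[-40, 40]$ to machine tolerance;
  achieved mean risk checked against the target at $10^{-6}$.
* IRLS: score norm $10^{-8}$, max 50 iterations; estimates with
  $|\hat\beta| > 15$ after convergence are reported as quasi-separation
  (a log odds ratio above 15 is not a credible finite estimate for binary
  screening factors).
* Test-suite problem sizes are chosen to keep binomial 3-sigma bands tight
  while remaining quick: 100,000-record simulations where the procedure is
  defined at that size (threshold derivation, parameter recovery, the
  Monte-Carlo-vs-enumeration check), 20,000 and below elsewhere; the DeLong
  null calibration uses 1,000 replicate cohorts of 500.
* The qualitative reclassification claim — that the Rothman-Keller model
  improves absolute NRI over the rule-based score when the data-generating
  truth is the weighted logistic model — is checked over 50 replicate
  cohorts of 11,692.

## Known limitations

The generator's independence and MCAR assumptions are idealisations; the
panel's PAR% values are literature inputs that cannot be re-derived from
the printed prevalences and odds ratios (Levin's formula gives e.g. 0.537
for hypertension against the tabulated 0.505); external-cohort quantities
(the published AUCs, Z statistics, NRI p-values and node scores) depend on
data and seeds that were never released and are therefore out of reach of
any reimplementation — the package validates procedure, arithmetic and
statistical behaviour instead.
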