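---
title: "Evaluating a binary CTG classification against term pregnancy outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a binary CTG classification against term pregnancy outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctgperf)
library(dplyr)
```

## The problem

Computerized antepartum cardiotocography (CTG) systems such as the
Dawes–Redman analysis reduce a fetal heart rate (FHR) trace to a binary
call: *criteria met* (consistent with fetal wellbeing) or *criteria not
met* (further evaluation advised). Evaluating such a call against what
actually happened at delivery is a diagnostic-accuracy problem on
observational data, and it inherits two classic complications:

1. **Confounding.** Traces from pregnancies that later had an adverse
   outcome differ systematically in gestational age, maternal
   characteristics, and how close to delivery the trace was recorded.
   A fair comparison needs cohorts balanced on those covariates.
2. **Prevalence dependence.** Predictive values computed on a matched 1:1
   sample (artificial 50% prevalence) say nothing about deployment, where
   the adverse-outcome prevalence may be 1–30% depending on the care
   setting.

`ctgperf` implements the full evaluation pipeline: eligibility-rule cohort
construction, 1:1 propensity-score matching with balance diagnostics,
prevalence-standardized diagnostic performance with confidence intervals,
and conditional logistic regression on the matched pairs — together with a
synthetic cohort generator so the whole pipeline is testable end to end
without access to clinical data (which in this setting cannot be shared).

## Cohort definitions

One row is one antepartum FHR trace from a term singleton pregnancy
(37+0–41+6 weeks at monitoring), recorded within 48 h of delivery. Traces
with more than 30% signal loss or an incomplete computerized analysis are
removed; all interval bounds are closed, so a trace at exactly 48.0 h or
30% signal loss is retained.

The **adverse pregnancy outcome (APO)** cohort contains every trace whose
neonate experienced at least one of seven outcomes: acidemia, stillbirth,
asphyxia, extended special-care (SCBU) admission, hypoxic-ischemic
encephalopathy, low Apgar scores (1-min < 4 or 5-min < 7), or neonatal
resuscitation. The resuscitation and extended-SCBU definitions arrive as
boolean inputs (set upstream from unit-level definitions); the low-Apgar
flag is derived from the scores.

The **normal pregnancy outcome (NPO)** cohort requires every inclusion
rule to pass — liveborn at term, maternal age 18–50, birth weight at or
above the 10th centile, labor under 24 h, Apgar scores of at least 4 and
7, cord acid-base status in the normal range (arterial pH > 7.13 with base
deficit < 10 mmol/L for Cesarean delivery without labor, pH > 7.05 with
base deficit < 14 mmol/L after labor), and a cerebroplacental ratio above
1.5 when one was measured — and no exclusion to fire (neonatal death
within 3 months, emergency Cesarean, breech, resuscitation, SCBU admission
or cooling, hypertensive disorders, suspected infection).

Three resolutions the rules need that the source description leaves open,
decided here once:

* **Missing inclusion evidence.** A record missing Apgar scores or cord
  gases cannot be *verified* normal and is ineligible for the NPO cohort;
  APO flags, by contrast, require affirmative evidence, so missingness
  never creates a case. This is the conservative reading.
* **Venous pH.** Thresholds are stated for arterial pH only. When arterial
  pH is missing, venous pH substitutes with the cutoffs shifted by a
  configurable `venous_ph_shift` (default +0.05, reflecting the typical
  veno-arterial difference).
* **APO precedence.** A record can carry an adverse-outcome flag (e.g.
  asphyxia alone) while passing every NPO screen. Such records are labeled
  APO and counted in the audit's `contradictions` rather than resolved
  silently.

```{r}
cohort <- generate_cohort(cohort_config(n_subjects = 2000, seed = 1))
labels <- build_cohorts(cohort)
cohort_audit(labels)$labels
head(cohort_audit(labels)$ineligibility_reasons, 3)
```

## Propensity model and matching

Cohort membership (APO = 1) is regressed on six covariates — gestational
age at monitoring, fetal sex, maternal BMI, maternal age, parity, and the
trace-to-delivery interval — by maximum-likelihood logistic regression on
sample-standardized covariates, including all pairwise interactions by
default (the interaction set is configurable; "interactions were
included" is the design statement, not an enumeration). Discrimination is
summarized by the AUC and calibration by the Brier score.

Matching is greedy 1:1 nearest-neighbour **on the logit of the propensity
score**, without replacement, with a caliper of 0.05 times the standard
deviation of the logit scores. The caliper phrase in the source
description conflates an absolute 0.05 with 5% of the logit SD; the SD
reading is the standard convention and is implemented, with the
multiplier configurable. Choices the method statement leaves open:

* *Processing order.* Greedy matching depends on the order cases are
  visited; cases are processed in a seeded random order and the seed is
  recorded on the result.
* *Neighbour index.* The published pipeline used a ball tree; on a
  one-dimensional logit axis the equivalent structure is a sorted array
  with binary search and an outward scan over still-available controls,
  which is what `match_pairs()` uses. A brute-force full-scan matcher in
  the test suite verifies exact agreement on small instances.
* *Ties.* Exact distance ties break toward the lexicographically smaller
  control id, for reproducibility.
* *Score clipping.* Fitted probabilities are clipped to [1e-8, 1 − 1e-8]
  before the logit transform so logit scores stay finite.

Balance is reported as standardized mean differences (SMD) per covariate
before and after matching, with SMD < 0.10 the conventional acceptability
threshold:

```{r, fig.width = 6, fig.height = 3.5}
model <- fit_propensity(cohort, labels)
pairs <- match_pairs(model, seed = 1)
bal <- balance_report(model, pairs)
bal
autoplot(bal)
```

## Performance metrics and prevalence standardization

A trace is *test-positive* when the call is `criteria_not_met`; a
pregnancy is *outcome-positive* when it belongs to the APO cohort.
Sensitivity, specificity and accuracy come from the matched confusion
matrix with Wald 95% intervals (Wilson available by flag). Because the
matched design pairs every case with a control, the accuracy interval
uses an effective sample size equal to the number of *pairs* (half the
trace count) by default; the conventional per-trace variant is available
via `accuracy_n = "traces"`. This pair-effective-n convention is what
reproduces the published accuracy interval from the published counts.

Predictive values are standardized to hypothetical deployment prevalences
by Bayes' rule,

$$\mathrm{PPV}(p) = \frac{\mathit{se}\,p}{\mathit{se}\,p + (1-\mathit{sp})(1-p)},
\qquad
\mathrm{NPV}(p) = \frac{\mathit{sp}\,(1-p)}{\mathit{sp}\,(1-p) + (1-\mathit{se})\,p},$$

with the four theoretical risk strata 1%, 10%, 20% and 30% as the default
profile and 5% for subgroup analyses. At the matched sample prevalence
(p = 0.5) these expressions collapse exactly to the raw confusion-matrix
ratios. Their intervals use the logit/delta method for case-control
designs (Mercaldo and colleagues):

$$\operatorname{var}(\operatorname{logit}\mathrm{PPV}) =
\frac{1-\mathit{se}}{\mathit{se}\,n_1} + \frac{\mathit{sp}}{(1-\mathit{sp})\,n_0},
\qquad
\operatorname{var}(\operatorname{logit}\mathrm{NPV}) =
\frac{\mathit{se}}{(1-\mathit{se})\,n_1} + \frac{1-\mathit{sp}}{\mathit{sp}\,n_0},$$

where $n_1$ and $n_0$ are the case and control sample sizes. A numerical
note: published NPV intervals for this evaluation are substantially wider
than the NPV variance above produces and are instead consistent with the
PPV variance having been applied to both predictive values; `ctgperf`
implements the correct per-value variances, so its NPV intervals at
prevalences above 1% are narrower than the published ones. The package's
interval coverage is property-tested by simulation (93–97% empirical
coverage at the study's sample sizes).

```{r}
cm <- confusion_matrix(tp = 301, fp = 155, fn = 1357, tn = 1503)
perf_report(cm)
```

Stratified reports partition traces into the [0, 24) h and [24, 48] h
trace-to-delivery windows, or evaluate each adverse outcome's cases
against all controls (subgroups overlap when outcomes co-occur). Strata
are compared with a 1-df two-proportion chi-square test without
continuity correction (configurable), falling back to Fisher's exact test
when an expected cell drops below 1. Predictive values at a fixed
theoretical prevalence are deterministic functions of the two operating
points, so their comparison is interpreted as a delta-method z-test on
the logit of the adjusted values. Continuous descriptors are compared
with the two-sided Mann–Whitney U-test. No multiplicity adjustment is
applied, matching the source analysis.

## Conditional logistic regression

The association between the CTG call and outcome status across matched
pairs is estimated by conditional logistic regression, which conditions
out the per-pair nuisance parameters. For a 1:1 design with binary
exposure only discordant pairs inform the estimate, and the maximizer has
the closed form $\hat\beta = \log(n_{10}/n_{01})$ with Wald standard
error $\sqrt{1/n_{10} + 1/n_{01}}$. The fitter maximizes the conditional
log-likelihood by Newton–Raphson with step-halving (tolerance $10^{-10}$,
50 iterations) and is verified in the tests against the closed form, a
grid-search maximizer, and `survival::clogit()`. The model is the
single-exposure matched-pair model; whether the source analysis included
further covariates is not stated, and none are added here.

```{r}
fit <- fit_conditional_logit(pairs, cohort)
fit
odds_ratio(fit)
```

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* the pipeline
assumes, not FHR physiology:

* **Covariate marginals** match the published cohort descriptors: BMI
  lognormal with median 25.9 and IQR 22.6–30.1 kg/m²; maternal age
  truncated normal with median 31 and IQR 27–35 years; 56.6% male; parity
  zero-inflated Poisson (median 0, IQR 0–1); gestational age uniform over
  259–293 days; trace-to-delivery interval uniform over [0, 48] h. Only
  medians and IQRs are published, so the distribution shapes are free
  choices, made once and documented here.
* **Confounding** enters through a logistic outcome model on standardized
  covariates with configurable log-odds weights (defaults of magnitude
  0.1–0.35, strongest on BMI, interval, and maternal age), the intercept
  calibrated by root-finding so the marginal APO fraction hits the
  configured prevalence. Zero weights give an unconfounded cohort.
* **Test behavior** is drawn with configurable sensitivity and
  false-positive rate. An optional logit-linear decay in the
  trace-to-delivery interval emulates the published fall in sensitivity
  from the 0–24 h to the 24–48 h window;
  `calibrate_sensitivity_decay(0.23, 0.132)` solves for the baseline and
  slope that hit those window means under a uniform interval
  distribution. The published gradient is reported, not mechanistically
  explained, so the logit-linear form is a modeling choice.
* **Outcome fields** are drawn consistent with the assigned flags
  (acidemic neonates get acidemic gases, stillbirths are not liveborn,
  and so on); non-APO subjects satisfy the NPO rules with high
  probability, with a configurable fraction forced to violate a random
  rule so exclusion paths are exercised. The generator emits one trace
  per pregnancy — how repeat traces were handled in the source data is
  not stated, and longitudinal structure is out of scope.

What passing tests on this generator do **not** show: real FHR traces are
not simulated, covariate dependence in real data is richer than the
independent marginals used here, and real missingness is unlikely to be
completely at random. The generator validates the *pipeline machinery*
(rule engine, matcher, estimators), not the clinical claims.

`demo_cohort()` deserves a separate note: it is a synthetic
reconstruction whose labeling reproduces the published matched-cohort
count structure exactly — 1658 APO and 1658 NPO traces with 301 and 155
positive calls — so the published performance table can be recomputed
end-to-end from a table the package builds in code.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 2 000 to
20 000 subjects — large enough that empirical rates sit within three
binomial standard errors of their targets, small enough to re-run
routinely. Simulation-based checks (interval coverage, parameter
recovery) use 1 000–2 000 replicates under fixed seeds. All percentages
render at one decimal place with round-half-even; interval endpoints are
never clamped except into [0, 1]; every stochastic step (generation,
match order) is governed by a single recorded seed.

## Known limitations

* The greedy matcher is order-dependent by construction; optimal
  (non-greedy) and k:1 matching are out of scope.
* The published AUC (0.67) and Brier score (< 0.01) for the propensity
  model describe the study data; a Brier score below 0.01 is atypical for
  a balanced binary outcome and cannot be reproduced or verified
  synthetically. It is recorded as a diagnostic, not targeted.
* Birthweight centiles, singleton status, and the extended-SCBU
  definition are inputs, not computed.
* Per-outcome stratified counts for the source data are not published, so
  per-outcome results can only be checked structurally.
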