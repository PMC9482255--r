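---
title: "Silva-based recurrence risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silva-based recurrence risk models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silvarisk)
```

## The clinical problem

Endocervical adenocarcinoma behaves differently from squamous cervical
cancer, yet postoperative adjuvant-therapy decisions for both rely on the
same intermediate-risk trigger, the Sedlis criteria, built from three
factors: lymphovascular space invasion (LVSI), depth of stromal invasion
(DSI, in thirds of stromal thickness) and tumor size. The Silva system
classifies the stromal invasion pattern of adenocarcinoma into A
(non-destructive), B (focally destructive) and C (diffusely destructive),
and pattern C carries most of the recurrence risk. This package
operationalizes a Silva-aware alternative: dichotomize the candidate risk
factors at clinical cut points, enumerate every k-of-m rule over them in
three families, score each rule on censored recurrence-free survival
(RFS), and compare the whole field — including the Sedlis criteria — on
one cohort.

The analysis universe is the *intermediate-risk* cohort: patients with
none of the three high-risk factors (nodal metastasis at any station,
positive surgical margin, parametrial involvement). High-risk patients
receive chemoradiation regardless, so rules are only useful below that
line.

## The rule models

A cutoff variable is a named binary predicate over a patient record.
The screening grid holds 16 of them: age at 40/50/60 years; Silva
"B + C" and "C"; tumor size at 2–5 cm by 0.5 (inclusive thresholds); DSI
strictly above 1/3 or 2/3 of stromal thickness; LVSI "any" and
"substantial only". A rule model is a variable set plus a threshold k:
the patient is positive when at least k member variables are true.

Three families are enumerated exhaustively from the six variables that
survive screening (Silva B + C, Silva C, ≥3 cm, ≥3.5 cm, DSI > 2/3,
> mild LVSI):

* **four-factor** — all four factor slots filled, one variant each:
  2 Silva × 2 size × k ∈ {2, 3, 4} = 12 models;
* **three-factor** — Silva replaces exactly one of size/DSI/LVSI:
  (2 + 4 + 4) variable sets × k ∈ {1, 2, 3} = 30 models;
* **two-factor** — Silva plus one other factor:
  (4 + 2 + 2) sets × k ∈ {1, 2} = 16 models.

The four-factor k range is fixed by the family's three published groups
("any 2", "any 3", "all 4"). The smaller families' k ranges are not
published; k ∈ {1, 2, 3} and k ∈ {1, 2} are the unique uniform choices
that reproduce the printed 30 and 16 counts from the replace-with-Silva
construction, and both are overridable in `model_config()`. The smaller
families always contain a Silva variant — the construction replaces
factors *with* Silva, so the pure {size, DSI, LVSI} triple is excluded.

```{r enumerate}
length(enumerate_models("four_factor"))
model_label(rule_model(c("silva_C", "size_ge_3", "dsi_gt_2_3",
                         "lvsi_gt_mild"), 3, "four_factor"))
```

### Threshold conventions

Three boundary decisions are deliberate and consistent throughout:

* **"> mild LVSI" means substantial only.** LVSI is graded
  none < mild < substantial; "strictly greater than mild" is the literal
  reading. Because the intent could also be "any LVSI", the `≥ mild`
  variant stays in the candidate set and is selectable in
  `cutoff_config()`.
* **DSI cut points are strict** on the continuous fraction: a patient at
  exactly 2/3 is negative for "DSI > 2/3". The DSI thirds used by the
  Sedlis logic are left-open/right-closed, so exactly 1/3 is superficial
  and exactly 2/3 is middle — consistent with the strict model variable.
* **Size thresholds are inclusive**: a 3.0 cm tumor satisfies "≥ 3 cm",
  and the Sedlis size clauses (≥ 2, ≥ 5, ≥ 4 cm) are inclusive as
  printed.

The Sedlis criteria predate graded LVSI, so `sedlis_positive()` takes
*any* LVSI as positive; the graded "> mild" notion applies only to the
new models.

## Survival statistics

All evaluation statistics are computed from first principles in the
package; the `survival` package appears only as an independent
cross-check in the test suite.

* **Kaplan–Meier / log-rank.** Product-limit estimation over distinct
  event times; the two-group log-rank accumulates observed minus
  expected events with the hypergeometric variance and refers
  `(O−E)²/V` to χ² on 1 df. Three-year rates are right-continuous
  evaluations of the curve at 36 months.
* **Cox partial likelihood.** Newton–Raphson from β = 0, convergence
  when the score max-norm falls below 1e-9, at most 50 iterations, with
  step-halving whenever a step would decrease the partial
  log-likelihood. Efron tie handling is the default because clinical
  follow-up in whole months produces many ties; Breslow is selectable,
  and the two agree exactly on tie-free data (a tested identity).
  Standard errors come from the inverse observed information; intervals
  and p-values are two-sided Wald at 0.05.
* **Degenerate fits are flagged, never hidden.** A rule that isolates an
  event-free group has a monotone partial likelihood; the coefficient is
  reported capped at ±15 with `degenerate = TRUE` rather than presented
  as a trustworthy finite estimate. Evaluations inherit the flag (empty
  group, event-free group, or unstable fit) and rank after all
  non-degenerate models.
* **Harrell's C.** A pair is comparable when the times differ and the
  earlier subject had the event; score ties count one half. The
  confidence interval is a seeded percentile bootstrap over subjects
  (1,000 replicates by default in `harrell_c()`, 200 inside the pipeline
  where 59 models are evaluated per run). The published analysis labels
  its discrimination statistic both "AUC" and "C index" with one shared
  value; this package computes Harrell's C and makes no attempt at a
  time-dependent ROC.

## Evaluation and ranking

`evaluate_model()` turns a rule into a binary indicator and reports the
univariate Cox HR with 95% CI and p, the two-group log-rank χ² and p,
Harrell's C with bootstrap CI, and the group/event counts.
`rank_models()` orders by descending C-index with a χ² tiebreak, then
model id; degenerate evaluations rank last. C-index leads because it is
the discrimination measure; in the motivating analysis the best model
maximized both statistics, so the data cannot distinguish the two keys.
Screening uses RFS at α = 0.05 with Silva B + C force-included
(mirroring its forced retention at a borderline p in the source
analysis); no multiple-testing correction is applied anywhere, matching
the reference workflow — the report carries the number of tests so a
reader can judge.

The drill-down of the best model uses **all-of-subset** semantics: for an
any-3-of-4 rule, each of the four 3-variable subsets is evaluated as a
conjunction, which asks *which* triple of factors carries the
discrimination.

## The synthetic cohort generator

The patient-level data behind the motivating analysis are not deposited,
so `generate_cohort()` provides cohorts with the structure the pipeline
assumes:

* a latent severity `U ~ Uniform(0, 1)` per patient;
* Silva pattern as the quantile cut of `U` at marginal probabilities
  27.8 / 26.1 / 46.1% — the published marginals, made deterministic in
  `U` so that every severity gradient across patterns is monotone;
* size (log-normal), DSI fraction (zero-inflated Beta), LVSI grade
  (ordered logit) and nodal/margin/parametrial/PNI/stage indicators
  (Bernoulli) all coupled to `U` on the logit scale with per-factor
  `dependence` strengths. Only marginal tables are published, so the
  coupling strengths are free parameters with documented defaults chosen
  to produce clear, plausible gradients (e.g. substantial LVSI is many
  times more frequent under pattern C than pattern B). Pattern-A
  patients are forced to LVSI none and PNI negative, matching the
  definitional absence of both in non-destructive invasion.
* recurrence times from a Weibull proportional-hazards model
  (shape 1.2, allowing a rising hazard; shape 1 recovers the
  exponential), linear predictor `Σ log_hr · indicator` over the four
  model-6 factors with default log-HRs (0.9, 0.6, 1.1, 0.7) ordered
  like the published multivariate fit; administrative censoring uniform
  over 36–168 months (the published follow-up span). The baseline scale
  (2,600 months) is calibrated once so that ≈9% of patients have an
  observed recurrence, the published recurrence fraction;
* overall survival as recurrence time plus an exponential
  post-recurrence survival draw (mean 24 months), so
  `rfs_months ≤ os_months` holds by construction and patients without
  recurrence are censored for both endpoints at the same administrative
  time. Cancer death without recurrence is not modeled.

Each field group draws from its own seed-derived RNG stream, so adding a
field never shifts the draws of existing fields.

```{r generate}
co <- generate_cohort(default_config(n = 345, seed = 1))
co
round(mean(co$rfs_event), 3)
```

**What passing tests do and do not show.** The generator reproduces
published *marginals*, a plausible monotone dependence structure, and a
proportional-hazards outcome mechanism. Real cohorts have joint factor
distributions, non-proportional hazards, loss to follow-up and
measurement error that it does not emulate; tests against synthetic data
therefore validate the *machinery* (statistics against oracles, counts,
determinism, error rates) and parameter recovery under the assumed
model, not the published patient-level estimates, which are not
reproducible without the original data.

## Simulation sizes and error-rate checks

The package's own calibration checks use sizes chosen to balance
statistical resolution against desk-scale runtimes: Wald-interval
coverage of a true HR = 2 uses 200 replicates of n = 2,000 (≈100 events
each); the screening type-I error uses 200 null replicates of n = 500
with a shorter baseline time scale (600 months) so each cohort carries
enough events (~12%) for Wald p-values to be meaningful; power and null
behavior of single evaluations use 5–10 replicates at n = 500–1,000.
Pipeline determinism is checked at n = 500 with 200 bootstrap
replicates.

## Known limitations

* The Cox implementation covers the univariate and modest multivariate
  fits the pipeline needs; stratification, time-varying covariates and
  robust variances are out of scope.
* Bootstrap C-index intervals are percentile intervals; no BCa
  correction.
* The generator's dependence structure is a single latent dimension;
  it cannot represent factors that are marginally correlated but
  conditionally antagonistic.
* With the published marginals and ~9% event fractions, small synthetic
  cohorts routinely produce degenerate strata (e.g. event-free rule
  groups). That is realistic — the motivating analysis shows the same
  instability in its sparsest strata — and it is why degenerate flags
  propagate to the ranking instead of being dropped.
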