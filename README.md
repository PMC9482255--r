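# silvarisk

Rule-based recurrence-risk modeling for intermediate-risk endocervical
adenocarcinoma, built around the **Silva pattern** of stromal invasion.

## The problem

After radical hysterectomy, adjuvant therapy for cervical cancer is
triggered either by a *high-risk* factor (nodal metastasis, positive
margin, parametrial involvement) or, among the remaining
*intermediate-risk* patients, by the **Sedlis criteria** — combinations
of lymphovascular space invasion (LVSI), depth of stromal invasion (DSI,
in thirds) and tumor size. The Sedlis criteria ignore histologic type,
and for adenocarcinoma the Silva classification (pattern A
non-destructive, B focally destructive, C diffusely destructive) carries
strong prognostic information that the criteria never see.

`silvarisk` implements the Silva-based alternative as a reusable
pipeline for anyone studying rule-based risk stratification on censored
survival data:

* **k-of-m rule models.** Candidate factors are dichotomized at
  clinical cut points (Silva B+C / C, size ≥ 3 / ≥ 3.5 cm, DSI > 2/3,
  > mild LVSI, …) and every rule "positive iff ≥ k of m factors present"
  is enumerated in three families — 12 four-factor, 30 three-factor and
  16 two-factor models.
* **Survival-based evaluation.** Each rule, and the Sedlis criteria, is
  scored on recurrence-free survival with a univariate Cox hazard ratio
  (Wald 95% CI, p), the two-group log-rank χ², and Harrell's
  concordance index with a bootstrap CI — all implemented from first
  principles (Kaplan–Meier, log-rank, Cox partial likelihood with
  Efron/Breslow ties, Harrell's C) and cross-checked against independent
  oracles in the test suite.
* **Ranking and drill-down.** Models rank by C-index (χ² tiebreak);
  the best model's size-k factor combinations are then compared
  head-to-head.
* **A synthetic-cohort generator.** The motivating patient-level data
  are not publicly deposited, so `generate_cohort()` produces cohorts
  with the published marginal structure (Silva 27.8/26.1/46.1%, ~9%
  recurrence, 36–168 month follow-up) and a latent-severity dependence
  among factors, driving Weibull proportional-hazards outcomes. The
  whole pipeline is exercisable and testable end to end.

## Worked example

```r
library(silvarisk)

cohort   <- generate_cohort(default_config(n = 345, seed = 42))
analysis <- run_full_analysis(cohort, analysis_config(seed = 1, n_boot = 200))
analysis
#> Silva-based recurrence-model analysis
#>   cohort: 345 patients, 85 high-risk excluded, 260 analyzed
#>   screened variables retained: 12 of 16
#>   evaluations: 59 (58 rule models + Sedlis)
#>   top-ranked: Any 2 of 4: Silva C, >=3.5 cm, DSI >2/3, >mild LVSI
#>     C = 0.750, chi-square = 33.624, HR = 9.418

analysis$ranking[1:3, c("rank", "family", "label", "hr", "chi_square", "c_index")]
#>  rank       family                                               label    hr chi_square c_index
#>     1  four_factor Any 2 of 4: Silva C, >=3.5 cm, DSI >2/3, >mild LVSI  9.42       33.6   0.750
#>     2   two_factor                       Any 1 of 2: Silva C, DSI >2/3 10.63       22.7   0.743
#>     3 three_factor               Any 2 of 3: Silva C, >=3 cm, DSI >2/3  8.22       28.4   0.738
```

Reading the output: of 345 synthetic patients, 85 carry a high-risk
factor and leave the analysis set. All 58 rule models plus the Sedlis
criteria are evaluated on the remaining 260. The winning rule here — a
four-factor model positive when any 2 of {Silva C, ≥3.5 cm, DSI > 2/3,
> mild LVSI} are present — separates recurrence hazards by a factor of
~9 and discriminates with C = 0.75, while the Sedlis criteria on the
same cohort rank 13th with C = 0.709. On synthetic cohorts the exact
winner varies with the seed; Silva-containing rules beating the Sedlis
criteria is the stable pattern, because the generator's risk is driven
by the four Silva-model factors.

`write_report(analysis, "report/")` writes the screen, per-family
evaluation tables, ranking and drill-down as TSV plus a JSON summary.
A command-line wrapper with `simulate` / `run` / `sedlis` / `enumerate`
subcommands lives at `inst/cli/silvarisk.R`.

See `vignette("silva-risk-models")` for the model conventions (strict
vs. inclusive thresholds, LVSI grading, tie handling, degenerate-fit
policy) and the generator's design.

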