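Package: silvarisk
Title: Silva-Pattern-Based Recurrence Risk Models for Intermediate-Risk
    Cervical Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating rule-based recurrence-risk
    models for intermediate-risk endocervical adenocarcinoma from the Silva
    pattern of stromal invasion, tumor size, depth of stromal invasion and
    graded lymphovascular space invasion. Provides cohort validation and
    CSV input/output, dichotomization of candidate risk factors at clinical
    cut points, exhaustive enumeration of k-of-m rule families, the Sedlis
    criteria as an executable reference rule, from-scratch censored-survival
    statistics (Kaplan-Meier, log-rank, Cox partial likelihood with Efron or
    Breslow tie handling, Harrell's concordance index with bootstrap
    confidence intervals), a synthetic-cohort generator with a latent
    severity structure and Weibull proportional-hazards outcomes, and a
    pipeline that screens variables, evaluates every rule against the Sedlis
    criteria, ranks the models and drills down the best one.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
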