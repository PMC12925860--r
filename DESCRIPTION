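Package: faceddm
Title: Drift-Diffusion Modelling of Face-Emotion Morph Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes binary happy-angry decisions on a 15-step face-emotion
    morph continuum with a drift-diffusion model whose drift rate varies
    linearly with morph index, yielding per-participant sensitivity (drift
    slope) and perceptual bias (the indifference point where drift vanishes).
    Provides the Wiener first-passage-time likelihood, maximum-likelihood
    fitting with multiple starts, trial- and participant-level quality
    control, group-level four-parameter logistic psychometric fits with an
    inflection-point comparison, Bonferroni-corrected correlation and ANOVA
    summaries, desk-scale linear/quadratic morph contrasts for ROI data, and
    a synthetic-data generator (task schedules, diffusion observers, clinical
    questionnaire cohorts with a target correlation structure, ROI betas)
    so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
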