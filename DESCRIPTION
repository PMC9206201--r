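Package: rhinodiary
Title: Scoring, Adherence and Data-Quality Indices for Allergic Rhinitis
    Symptom Diaries
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily electronic symptom diaries kept by
    patients with seasonal allergic rhinitis. Builds the three standard daily
    disease indices (Rhinoconjunctivitis Total Symptom Score, Combined
    Symptom and Medication Score, Visual Analogue Scale) from item-level
    entries, quantifies adherence to prescribed daily recording, computes
    four candidate data-quality indices on per-patient score trajectories
    (intravariation index, percentage of zero values, coefficient of
    variation, percentage of changes in trend), and compares index values
    between high- and low-adherence patients with nonparametric tests. A
    synthetic diary-cohort generator with ground-truth respondent-behaviour
    labels (including carry-forward "insufficient effort" responding) makes
    every pipeline stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
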