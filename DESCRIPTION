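Package: smmteams
Title: Shared Mental Model Similarity Scoring and Team-Level Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying shared mental models (SMM) in small
    interprofessional teams from nominal questionnaire responses. Computes
    pairwise-agreement similarity scores for single-choice items and
    set-overlap similarity (Jaccard, Dice, overlap coefficient) for
    multiple-choice items, aggregates them to domain- and team-level scores,
    and analyses pre/post training designs with a two-way mixed
    repeated-measures analysis of variance reporting partial eta squared.
    Includes baseline-balance tests, a priori paired sample-size
    calculation, and a seeded generative model of team responses for power,
    type-I-error and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
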