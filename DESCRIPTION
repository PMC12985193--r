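Package: distuq
Title: Distance-Based Epistemic Uncertainty Quantification for Binary Risk Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the epistemic uncertainty of binary risk
    classifications on tabular feature data by measuring per-label
    nearest-neighbour Manhattan (or Minkowski) distances to a labelled
    training cohort, scoring each candidate label with a distance-ratio
    uncertainty score, and mapping the result onto a GREEN/AMBER/RED
    traffic-light category relative to the training cohort's within-group
    distance distribution. Includes a prevalence-calibrated decision
    threshold for imbalanced cohorts, training-set distance summaries,
    a seeded synthetic feature-space scenario generator, per-case
    two-step clinical reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
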