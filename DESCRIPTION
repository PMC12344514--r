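Package: fcgroupsim
Title: Group-to-Individual Similarity of Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how well a group-averaged resting-state functional
    connectivity (rsFC) model represents each constituent individual, and how
    individual distinctness from the group moderates behavioral prediction.
    Builds ROI-based and network-based Fisher-z connectivity representations
    from parcellated time series (with motion censoring, temporal
    signal-to-noise ROI exclusion, and between-subject variance feature
    selection), scores per-subject similarity against the training-set group
    model with two-way random-effects absolute-agreement intraclass
    correlations (ICC(A,1)), runs a shuffled-network-assignment permutation
    null, fits cross-validated elastic-net models predicting behavioral
    outcomes from connectivity features, and tests whether group similarity
    moderates predictive performance via interaction regression with
    Johnson-Neyman regions of significance. Includes a synthetic-cohort
    generator with tunable between-subject heterogeneity and a known
    similarity-moderated brain-behavior coupling, so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
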