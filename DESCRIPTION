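Package: loomsync
Title: Collective Decision Analysis of Looming-Stimulus Responses in Small Fish Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for looming-stimulus (LS) escape assays in small
    groups of fish: reads multi-animal tracking coordinates, calibrates pixels to
    centimetres, builds smoothed velocity matrices, classifies each 10-second
    interval (before/during/after LS) into freezing-like, normal or high-speed
    states, computes Markov state-transition matrices and diagrams, tests the 27
    before/during/after transition patterns for enrichment with exact binomial
    tests under FDR control, tests group synchrony of post-LS freezing against a
    seeded shuffle null with a chi-square comparison, clusters group response
    profiles (PCA to >95% variance, spectral clustering with silhouette model
    selection) and compares freezing counts across clusters or conditions with a
    binomial-logit mixed model. Includes an agent-based generator of tank-swimming
    trajectories with tunable group-level consensus, so the whole pipeline is
    testable without raw video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    multcomp,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    kernlab,
    withr,
    yaml
Config/testthat/edition: 3
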