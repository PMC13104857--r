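Package: morphoscore
Title: Signature-Based Efficacy and Specificity Scoring for Single-Cell
    Morphological Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hit calling for high-content imaging screens directly from
    single-cell image-based profiles. Two control populations (a reference
    state, e.g. diseased cells, and a target state, e.g. healthy cells)
    are compared feature-by-feature with two-sample Kolmogorov-Smirnov
    tests under Benjamini-Hochberg false-discovery-rate control to derive
    an on-morphology signature (features separating the two states) and a
    complementary off-morphology signature. Every perturbation is then
    scored for efficacy -- the Earth Mover's Distance between its cells
    and the target population over the on-signature, normalised by the
    reference-to-target distance -- and for specificity, the fraction of
    off-signature features it significantly alters. Includes
    leave-one-gene-out evaluation with permutation controls, rank
    concordance (Kendall's W) against a label-permutation null,
    cross-plate replicate analysis, and a synthetic-screen generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    arrow,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
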