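Package: pdsubtype
Title: Atrophy-Based Subtyping of Parkinson's Disease from Multi-Cohort
    Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-mode (global-atrophy-unadjusted and -adjusted) subtyping of
    Parkinson's disease from regional gray-matter morphometry pooled across
    heterogeneous cohorts. Implements reference-group residual harmonization
    of FreeSurfer-style thickness and volume tables (field strength, head
    size, cohort), per-subject severity normalization, unsupervised
    random-forest proximity clustering with classical multidimensional
    scaling and average-linkage agglomeration, cluster-number selection by
    majority vote over internal validity indices, a cluster characterization
    battery (Kruskal-Wallis, chi-square, ANCOVA effect-size maps with FDR
    control, transition tables), and random-intercept mixed models for
    longitudinal motor and cognitive trajectories. Ships a synthetic
    multi-cohort generator with planted severity- and typicality-subtypes so
    the full pipeline is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    mclust,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
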