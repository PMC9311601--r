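Package: symmod
Title: Bilateral Symmetry and Modularity Analysis of Landmark Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics of structures with object
    symmetry: generalized Procrustes superimposition with reflect-relabel
    decomposition into symmetric and asymmetric shape components, Procrustes
    ANOVA with residual-randomization permutation inference, a triangle-area
    left-right asymmetry profile with per-pair Z-tests and between-sex
    comparisons, Mantel correlation of module-wise asymmetry, covariance-ratio
    (CR) modularity statistics with permutation effect sizes and pairwise
    modular-signal comparison, likelihood/AICc selection over covariation
    models, and modularity tests against arbitrary landmark partitions.
    Includes TPS file input/output and a synthetic landmark-data generator
    with known block covariance structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
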