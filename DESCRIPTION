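Package: faceforge
Title: Appearance Models, First-Impression Ratings and Extreme-Face Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gender-specific statistical appearance models (a shape PCA
    of Procrustes-aligned facial landmarks combined with a texture PCA of
    shape-normalised pixel intensities), aggregates judge ratings of first
    impressions into reliable mean scores with Cronbach's alpha, correlates
    ratings with self-reported personality via permutation tests, predicts
    mean trait ratings from facial components with cross-validated linear
    regression and correlation-based feature selection, and synthesises
    extreme faces along the regression gradient with a forced-choice
    validation statistic. Includes a fully parametric synthetic-cohort
    generator (cartoon faces with known latent factors, noisy judge panels,
    personality scores at stated effect sizes) so every stage of the
    pipeline is testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deldir,
    png,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
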