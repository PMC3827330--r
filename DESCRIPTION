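Package: latentpath
Title: Latent Correlations and Path Models for Longitudinal Attainment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of latent bivariate-normal correlations from
    observations that are exact, ceiling- or floor-censored, ordinal, or
    binary, using an adaptive Metropolis sampler with delayed rejection
    (unifying censored-normal, tetrachoric, polychoric, and biserial
    correlations); classical test-theory utilities (Cronbach's alpha,
    Spearman-Brown prophecy and its inverse, disattenuation, two-sample
    power); backwards-elimination path analysis with standardized
    coefficients; UK secondary-school grade-point scoring; and a synthetic
    longitudinal cohort generator with selection-based restriction of
    range, grade ceilings, ordinal grouping, and outcome-dependent exam
    uptake, for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
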