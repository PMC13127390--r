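Package: her2agree
Title: Inter-Rater Agreement Analysis for HER2 Immunohistochemistry Scoring Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing agreement among panels of pathologists scoring
    HER2 immunohistochemistry on the ordinal 0/1+/2+/3+ scale. Provides a
    validated case-by-observer score matrix container with CSV input/output,
    category merges and clinically motivated dichotomizations, "score assigned
    by at least one observer" case subsets with their rating and co-occurrence
    cross-tabulations, overall percent agreement with Wilson or Clopper-Pearson
    intervals, Fleiss' kappa with the Fleiss-Nee-Landis large-sample interval,
    the two-way random-effects absolute-agreement single-rater intraclass
    correlation ICC(A,1) with F-based intervals, ONEST observer-resampling
    curves with plateau estimation, and a seeded latent-class rater-panel
    simulator for testing and calibration without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
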