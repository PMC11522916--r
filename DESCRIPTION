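Package: reefsucc
Title: Coral Reef Succession Analysis with Trait-Space Diversity Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing succession of coral and reef-fish assemblages
    from line-intercept benthic transects and belt-transect fish counts.
    Computes percent cover from line-intercept surveys, Hill-number diversity
    with sample-coverage and rarefaction/extrapolation curves, Bray-Curtis
    ordination (PCoA), PERMANOVA and distance-based redundancy analysis with
    AIC forward selection, Gower-distance coral trait spaces with convex-hull
    occupied-volume, five-nearest-neighbour functional redundancy and
    abundance-weighted functional dispersion, kernel-density trait-space
    occupancy maps, and random-intercept linear mixed models with
    Satterthwaite tests of coral-fish relationships. Includes a synthetic
    survey generator emulating a multi-year reef degradation and recovery
    study so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
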