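Package: vegshift
Title: Compositional and Structural Change in Repeat-Visit Point-Intercept
    Vegetation Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how plant communities change between
    repeated visits to permanent one-hectare monitoring plots surveyed with
    the point-intercept method (10 transects of 101 points, 1010 point
    intercepts per visit). Converts raw intercept records to per-visit
    community profiles (percentage cover, transect frequency, importance
    value index), computes Bray-Curtis (Sorensen) and Simpson beta
    dissimilarities between baseline and revisit surveys, regresses
    dissimilarity on survey interval and annualises turnover rates, fits
    lognormal species abundance distributions to classify dominance shifts,
    and tallies structural (growth-form and vegetated-area) change. Includes
    a seedable simulator of repeat-visit surveys with known turnover for
    validation, and an end-to-end report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
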