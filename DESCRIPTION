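Package: roavtools
Title: Relative Odor Activity Value Analysis of Volatile Compound Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for aroma profiling of fermentation volatiles from
    GC-MS compound tables and electronic-nose sensor arrays. Normalizes
    peak areas to relative contents, manages odor detection thresholds
    (point, interval, and approximate values) with curated carbon-chain
    homolog bracketing for unknown ester thresholds, scores compounds by
    relative odor activity value (ROAV) against the strongest contributor,
    classifies key/modified/potential odor compounds, compares strains by
    their key-compound sets and aroma notes, and analyzes 10-sensor
    electronic-nose response matrices by PCA and linear discriminant
    analysis. Includes a synthetic-data generator with known ground truth
    for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
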