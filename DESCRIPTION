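Package: glycoratio
Title: Isotope-Ratio Quantitation of Derivatized Serum N-Glycomes from MALDI-TOF Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for serum N-glycome quantitation
    with per-glycan deuterium-labeled internal standards. Builds a theoretical
    mass library for linkage-derivatized glycan compositions (ethyl-esterified
    alpha-2,6 and lactonized alpha-2,3 sialic acids, with optional O-acetyl
    modification), extracts light/heavy intensity ratios from MALDI-TOF peak
    lists after affine mass recalibration, applies coefficient-of-variation and
    Tukey-fence quality control, computes derived glycosylation traits from a
    declarative trait registry, and compares diet groups with unpaired t-tests.
    Includes a synthetic-data generator that emulates a two-group longitudinal
    mouse study design for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
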