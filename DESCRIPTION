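Package: limbalign
Title: Automated Lower-Limb Alignment Measurement from Long-Leg Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of lower-limb alignment for knee
    osteoarthritis assessment. Detects ten anatomical landmarks per limb on
    anteroposterior long-leg radiographs with a compact two-branch network
    (Gaussian-heatmap regression plus an edge-vector constraint head over a
    shared multi-resolution backbone), converts landmarks into the five
    clinical alignment angles (HKA, JCLA, AMA, mLDFA, mMPTA) with a documented
    sign convention, classifies limbs as varus/neutral/valgus, and evaluates
    agreement against reference annotations with mean radial error, mean
    absolute difference, angle-deviation rates, Bland-Altman limits of
    agreement and Pearson chi-square subgroup tests. A parametric phantom
    generator renders synthetic long-leg radiographs with exactly known
    landmarks and angles so the whole pipeline trains and validates without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
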