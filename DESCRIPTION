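Package: centiloidr
Title: Level-2 Centiloid Calibration for Amyloid-PET SUVR Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for harmonizing amyloid-PET standardized uptake value
    ratios (SUVR) onto the Centiloid scale via site-specific ("level-2")
    linear calibration. Includes dynamic-frame windowing of 4D PET series
    into late-uptake static images, volume-of-interest SUVR quantification
    under mean- and median-based conventions, ordinary least squares and
    Deming errors-in-variables regression with transform inversion and
    composition, one-step and two-step calibration pathways, Centiloid-unit
    conversion anchored at young-control and Alzheimer's-disease group
    means, tolerance-checked calibration reports, and synthetic paired-SUVR
    and dynamic-phantom generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
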