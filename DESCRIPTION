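Package: nematiq
Title: Nematic Cell Polarity and Biaxial Co-Orientational Order in 3D Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies membrane-domain surface patterns on single cells by their
    spherical-harmonic power spectrum (vectorial versus nematic polarity), extracts
    nematic polarity axes (ring and bipolar axes) from the nematic tensor of the
    radially projected pattern, and quantifies biaxial orientational order in
    three-dimensional tissues with the classical liquid-crystal order parameters
    (S, P, D, C) and with co-orientational order parameters (co-S, co-P, co-D, co-C)
    measured against per-cell reference frames. Includes the anisotropy tensor of a
    segment network (e.g. liver sinusoids), a punctured-Gaussian local reference
    field, a minimal Boltzmann co-alignment model with coupling-strength recovery,
    and synthetic generators for every input so the full pipeline runs without
    external data.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
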