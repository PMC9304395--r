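Package: mechamap
Title: Micromechanical Stiffness Mapping of Tissue from AFM Force Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for micrometer-scale mechanical analysis of soft tissue
    probed by atomic force microscopy (AFM) force spectroscopy. Simulates
    force-distance indentation cycles over gridded force maps with realistic
    acquisition artifacts, extracts Young's moduli by fitting the Hertz
    spherical-indenter contact model with joint contact-point refinement,
    applies per-curve quality-control filters, scores force-map coverage with
    a nearest-neighbour distance index, and compares stiffness across tissue
    types and clinical covariates using hierarchical gamma generalized linear
    mixed models fitted by penalized quasi-likelihood with Wald F tests.
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
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
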