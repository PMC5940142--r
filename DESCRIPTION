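Package: surfqtl
Title: QTL Mapping and Shape Analysis of Nonlinear Stress-Response Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTL) that change the
    shape of a plant's growth response to combined drought and nitrogen
    stress. Implements per-marker quadratic response-surface fits with a
    kinship-structured random line effect, an F-test genome scan with
    Simes smoothing and Sidak/FDR multiplicity control, a five-parameter
    producing-function model of surface shape (elliptical paraboloid plus
    tilted plane), mesh-based parameter estimation, and mesh-based
    similarity scoring of surface shapes. A synthetic-data generator
    emulates a biparental recombinant-inbred experiment under a
    face-centered response-surface design so the full pipeline can be
    exercised without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
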