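Package: qtlhotspots
Title: GWAS Marker-Trait Associations and LD-Calibrated QTL Hotspots for
    Structured Wheat Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to take multi-year agronomic and UAV-derived vegetation-index
    phenotypes of a structured bread-wheat panel from raw plot records to
    quantitative trait locus (QTL) hotspots. Provides a synthetic-data generator
    with known ground truth (Balding-Nichols structured genotypes with
    map-consistent linkage disequilibrium, augmented-design multi-year
    phenotypes with planted QTLs, and four-band canopy reflectances), marker
    quality control, the six standard spectral vegetation indices with
    MTVI2-based leaf area index calibration, REML variance components and
    broad-sense heritability, an EMMA-style mixed-linear-model association scan
    (principal components plus kinship, P3D), and the QTL overview index with
    LD-decay Gaussian confidence intervals, peak calling, hotspot merging and
    exclusion rules, and physical-interval arithmetic with gene-model lookup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    lme4,
    vcfR,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
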