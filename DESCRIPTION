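Package: xylemhydro
Title: Xylem Hydraulic Trait Analysis for Coarse Roots and Branches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives xylem hydraulic traits from wood-anatomical and
    gravimetric flow measurements of tree roots and branches, and runs the
    comparative statistics used in organ- and leaf-habit-level trait studies.
    Anatomical traits (conduit density, lumen fraction, hydraulically
    weighted conduit diameter, Hagen-Poiseuille potential conductivity) are
    computed from conduit lumen measurements in radial sectors of
    cross-sections; empirical axial and xylem-specific conductivities,
    leaf-specific conductivity and Huber values are derived from flow-meter
    records and segment geometry; wood density from segment or increment-core
    geometry and dry mass. The inference layer provides tree-wise averaging,
    marginal-mean contrasts between leaf habits and organs, Tukey compact
    letter displays, Pearson trait correlation matrices, root-to-branch trait
    ratios and a random-intercept model of trait-height relationships. A
    calibrated synthetic-study generator and a synthetic cross-section
    renderer with segmentation-based re-measurement make every pipeline stage
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    multcomp
Config/testthat/edition: 3
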