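Package: toothface
Title: Volumetric Tooth-Face Superimposition and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional correspondence between the
    buccal surface of the maxillary central incisor and facial shape by
    volumetric superimposition: the buccal patch is extruded to a watertight
    solid, scaled by the bizygomatic-to-tooth width ratio, aligned to the
    facial scan through anatomical landmarks, and intersected with the
    closed facial solid; the remaining tooth volume (RTV) and the
    superimposition percentage (%SI) summarise the fit. Includes triangle
    mesh infrastructure (STL I/O, signed volumes, rigid transforms, BSP
    Boolean intersection, voxel-column volume oracle), the cohort
    statistics battery (descriptives, Shapiro-Wilk gating, Spearman,
    paired and two-sample t with Levene gating, Mann-Whitney, effect
    sizes, achieved power via noncentral t and Fisher z), and seeded
    synthetic generators for tooth patches, facial shells with landmarks,
    and copula-correlated cohort tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
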