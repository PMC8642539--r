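Package: invadR
Title: Quantification of Tumor Cell Invasion into Brain Organoids and
    Companion Single-Cell Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Open implementation of a 3D image-analysis pipeline that
    quantifies glioblastoma cell proliferation and invasion in cleared
    brain-organoid co-cultures: blank-slice padding, two-pass organoid
    surface reconstruction from the nuclear channel, scale-matched tumor
    spot detection, exact signed point-to-mesh shortest distances, and
    the downstream invasion statistics (per-organoid min-normalization,
    reference-group third-quartile invasion threshold, invading-cell
    counts, stacked kernel density profiles, t tests and one-way ANOVA
    with Tukey HSD). A second arm covers defined single-cell
    computations for xenograft droplet data: dual-species barnyard
    assignment, detected-gene and mitochondrial QC filtering, binned
    control-gene cell-cycle module scoring with G1/S/G2M phase binning,
    treatment-arm proportion shifts, and volcano-plot category
    classification. Seeded synthetic generators for ground-truthed 3D
    organoid scenes and dual-species UMI count matrices replace
    microscopy and sequencing inputs so every stage is testable against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
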