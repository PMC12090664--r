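Package: tomodrift
Title: Dosimetric Consequences of Unmanaged Intrafraction Target Drift in
    Helical Tomotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the dose a patient would have received if intrafraction
    target motion (e.g. prostate drift) had gone unmanaged during helical
    tomotherapy delivery. Builds slice-wise deformation vector fields that
    account for the interplay between continuous couch translation and target
    motion, warps planned dose grids by voxel-wise trilinear resampling,
    assembles fraction-wise and worst-case unmanaged-motion scenarios
    (including renormalization to an ultra-hypofractionated regimen with a
    contracted mock target), and reports dose-volume-histogram metrics
    (D95%, V95%, median dose). Includes readers and writers for a documented
    motion-trace CSV dialect and NRRD volumes, Euclidean margin operations on
    structure masks, and a seeded synthetic generator for plans and
    plateauing drift traces so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    grDevices,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
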