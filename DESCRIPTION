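Package: pethet
Title: Proliferative Heterogeneity Analysis for FLT-PET Tumor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies early treatment response in heterogeneous tumors imaged
    with [18F]FLT positron emission tomography. Provides muscle-referenced
    proliferative voxel classification of SUV volumes, fractional-frequency
    histogram analysis of tumor voxel intensity distributions with two-sample
    Kolmogorov-Smirnov comparison, caliper-based xenograft growth-curve
    analysis with nonparametric cohort statistics and Grubbs outlier
    screening, and dose-response viability quantification for plate assays.
    Includes a seeded synthetic phantom and study generator emulating necrotic-
    core tumor geometry, so the full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
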