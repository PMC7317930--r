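Package: goldquant
Title: Quantitative Analysis of Immunogold Labeling in Replica and
    Pre-Embedding Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and quantification pipeline for immunogold
    electron microscopy of membrane receptors. Generates synthetic
    SDS-digested freeze-fracture replica (SDS-FRL) and pre-embedding
    scenes with known ground truth (clustered plus scattered gold
    particle point patterns on compartment profiles, rasterized as
    micrograph-like images), detects 10 nm gold particles with a
    multi-scale blob detector, estimates compartment-wise surface
    densities (particles per square micrometre) with E-face background
    correction, partitions labeling between active-zone and
    extrasynaptic presynaptic membrane and between plasma-membrane and
    intracellular sites, computes cluster statistics (minimum cluster
    size three, convex-hull area, nearest-cluster distance, composition
    histograms), quantifies histoblot and immunoblot densitometry with
    multi-ROI background subtraction, and compares groups by two-way
    ANOVA with Bonferroni post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
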