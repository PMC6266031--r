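Package: pencilbeam
Title: Pencil-Beam Dose, LET and Biological Dose Engine for Scanned Ion Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward dose calculation for actively scanned proton and
    carbon-ion beams. Computes physical dose on a voxel phantom with a
    depth-dependent triple-Gaussian lateral kernel, water-equivalent-path-length
    raytracing at CT resolution, optional range-shifter handling and
    sub-pencil-beam splitting for heterogeneous geometries. Accumulates
    dose-averaged LET and the mixed-field quantities needed for RBE-weighted
    dose under a fixed RBE of 1.1 (protons) or the Local Effect Model and
    modified Microdosimetric Kinetic Model (carbon ions). Ships a synthetic
    per-energy beam database generator, a spread-out-Bragg-peak spot-weight
    optimizer, and an evaluation suite: cumulative dose-volume histograms,
    D_x / LET_d,x metrics, 3-D gamma-index analysis and the 12-chamber
    patient-QA statistic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
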