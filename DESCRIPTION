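Package: mvochip
Title: Microvascular Obstruction Drug-Delivery Analysis in a Microfluidic Chip Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies catheter-based drug delivery around microthrombi in a
    microfluidic model of cardiac microvascular obstruction (MVO). Builds a
    bifurcating arteriolar chip network, solves lumped Poiseuille flow with
    distal-resistor tuning and 1-D advection-diffusion dye transport, renders
    synthetic backlit video frames with ground truth, recovers per-pixel dye
    concentration by per-pixel calibration, constructs annulus regions of
    interest around detected microthrombi, computes dose metrics (maximum
    concentration and cumulated dose), classifies thrombus occlusivity and
    drug contact, and compares balloon versus no-balloon infusion protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
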