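Package: serialed
Title: Serial Electron Diffraction Processing and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for serial electron nanocrystallography
    (SerialED): crystal mapping on STEM overview images, dose-fractionated
    still-diffraction preprocessing, Bragg peak detection with radial
    background estimation, known-cell still indexing by orientation search,
    Monte-Carlo merging with serial-crystallography statistics (R_split,
    CC1/2, CC*), and radiation-damage / optimal-dose analysis. Includes a
    physics-based simulator (flat Ewald sphere, Wilson structure factors,
    per-shell exponential damage, Poisson counting noise, detector defects)
    so the full chain is testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
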