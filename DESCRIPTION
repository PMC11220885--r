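Package: spirecon
Title: Predicted-Model-Aided Reconstruction for XFEL Single-Particle Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for X-ray free-electron laser (XFEL) single-particle imaging:
    simulation of snapshot diffraction patterns from atomic models with Poisson
    noise and a beam stop, orientation determination by correlation maximization
    against a reference Fourier volume seeded from a predicted atomic model,
    merging of oriented Ewald slices into a three-dimensional intensity, and
    electron-density recovery by hybrid input-output / error-reduction phase
    retrieval with a cubic support and floating missing data. Includes Fourier
    shell correlation, CC-shell, phase-retrieval transfer function and
    angular-deviation diagnostics, plus download-free phantom fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
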