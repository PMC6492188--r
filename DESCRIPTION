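Package: dager
Title: Gaussian-Process Constrained k-q Reconstruction for Accelerated
    Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint k-q reconstruction of highly accelerated diffusion MRI.
    Parallel-imaging inversion (SENSE and simultaneous-multislice SENSE) is
    constrained by a Gaussian-process prior over q-space whose smoothness
    hyper-parameters are learned from the data by marginal-likelihood
    estimation.  Includes the complementary k-q sampling designer based on
    graph coloring, a fully synthetic acquisition simulator (ball-and-stick
    phantoms, simulated coil arrays, complex k-space noise, per-volume
    motion phase errors), quantitative evaluation tools, and a command-line
    interface, so the complete method can be exercised without scanner
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
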