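Package: nirphantom
Title: Characterization Toolkit for Near-Infrared Fluorescent Tissue-Simulating Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational characterization chain for solid tissue-simulating
    fluorescence phantoms and the imagers they qualify. Provides a white
    (zero-absorption) photon-packet Monte Carlo model of time-resolved diffuse
    transmittance through a slab, a closed-form time-domain diffusion oracle,
    lookup-table inversion of absorption and reduced scattering coefficients
    from photon time-of-flight distributions, scan-grid homogeneity mapping,
    fluorescence-imager photostability and photobleaching quantification,
    spectral background subtraction and concentration-linearity analysis, and
    a synthetic-data generator that emulates the measurement chain for
    truth-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
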