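Package: ramantrap
Title: Automated Single-Particle Raman Trapping: Acquisition Control,
    Preprocessing, Marker-Mediated Sizing and Mixture Chemometrics
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Software stack for automated single-particle Raman trapping
    experiments. Provides an acquisition state machine with trap-recognition
    thresholding and laser-disabling logic, a physics-based virtual instrument
    that renders trapped-particle spectral streams with Brownian
    escape/arrival kinetics, the standard spectral preprocessing chain
    (cosmic-spike repair, asymmetric-least-squares Whittaker baseline,
    Savitzky-Golay smoothing, area normalisation), perchlorate
    volume-displacement particle sizing with calibration and inversion, and
    mixture-resolution chemometrics (two-component Gaussian mixture EM, PCA,
    Ward clustering, PLS-DA with venetian-blinds cross-validation) plus
    dynamic reaction-trace analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
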