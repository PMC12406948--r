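Package: mpsquant
Title: Magnetic Particle Spectroscopy Simulation, Quantification and
    Contamination Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for magnetic particle spectroscopy (MPS) of iron-oxide
    nanoparticle tracers. Simulates nonlinear time-domain magnetization
    responses of superparamagnetic nanoparticles (Langevin equilibrium with
    Debye relaxation), hysteretic ferromagnetic contaminants, and blank
    measurements; extracts odd-harmonic amplitude and phase spectra; converts
    third-harmonic moments to iron mass via reference calibration with an
    IUPAC blank-based limit of detection; classifies specimens by their
    (A5/A3, phi3) spectral fingerprint to exclude dietary magnetic
    contamination; and summarizes corrected biodistribution studies.
    Includes a synthetic organ-panel study generator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
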