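Package: hhsd
Title: Hodgkin-Huxley Models Linking a Sodium-Channel Gating Defect to
    Spreading Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based neuron models spanning three time scales:
    the classical Hodgkin-Huxley action-potential model, an
    ion-concentration-resolving model of spreading depression with a
    Na/K-ATPase pump and potassium bath coupling, and an extended anoxic
    depolarization model with glial buffering and blood diffusion.  A
    familial-hemiplegic-migraine (FHM3, Nav1.1) gating defect is modelled
    as a voltage-dependent rescaling of the sodium inactivation time
    constant (f-fold slower inactivation, f-fold faster deinactivation).
    Includes equilibrium continuation with Hopf-point detection (rheobase
    and excitation block), firing-rate curves, simulated voltage-clamp
    measurement of inactivation time constants, pump-interruption and
    anoxia protocols, and feature extraction (spike detection, spreading
    depression classification, critical-window measurement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
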