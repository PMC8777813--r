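Package: sonosim
Title: Microbubble Dynamics, Acoustics and Dose-Response Analysis for Sonoporation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing shell-stabilized ultrasound contrast agents
    (SonoVue, Sonazoid, Optison) in low-intensity sonoporation studies:
    tone-burst synthesis and acoustic-output metrics (MI, I_SPPA, I_SPTA),
    a modified Rayleigh-Plesset model for encapsulated microbubbles with
    equilibrium-radius sweeps and size-distribution weighting, constant-rate
    infusion pharmacokinetics, optical particle-sizing analytics,
    attenuation and cavitation spectral analysis with four-parameter
    logistic threshold fitting, and interpolated best-agent dose-response
    maps. Includes seeded synthetic-data generators so every analysis stage
    can be exercised and validated without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
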