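Package: sigbnet
Title: Pulsatile Dynamics of the Sigma-B General Stress Response Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action model of the Bacillus subtilis sigma-B
    partner-switching network with autoregulated operon synthesis.
    Provides deterministic and stochastic simulation of the stress
    phosphatase input (step, ramp, and gamma-distributed
    Ornstein-Uhlenbeck burst processes), decoupled post-translational
    and transcriptional response analysis with logarithmic gains and
    feedback-region classification, pulse detection and Hill-equation
    fitting for burst-size/frequency and ramp-rate encoding
    experiments, and RNA-polymerase competition models coupling
    sigma-B to the housekeeping factor sigma-A and a second stress
    factor sigma-W.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
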