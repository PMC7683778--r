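Package: mddsloops
Title: Feedback-Loop Models of Mal de Debarquement Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the feedback-loop account of Mal de
    Debarquement Syndrome (MdDS): Monte-Carlo spectral analysis of a
    structured random Jacobian ensemble for a bilateral vestibulocerebellar
    loop network, a nonlinear firing-rate realisation of the same circuit, a
    postural control model with an internal-model adaptation oscillator that
    cancels sinusoidal disturbances, and a bistable positive-feedback model
    of synaptic long-term potentiation whose state strengthens the network's
    inhibitory connections. Includes reproducible sweep experiments,
    time-domain verification oracles, and an end-to-end scenario chaining
    plasticity, network oscillation probability, and posture dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
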