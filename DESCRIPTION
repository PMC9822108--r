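Package: neurometab
Title: Mechanistic Modelling of Visual-Cortex Metabolism and
    Neurovascular Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic ordinary-differential-equation modelling of
    stimulated central metabolism in the human visual cortex and its
    coupling to a neurovascular model with a BOLD observable. Provides
    forward simulation of metabolite and BOLD percent-change responses
    to visual-stimulation paradigms, maximum-likelihood parameter
    estimation with chi-squared model rejection, MCMC prediction
    uncertainty envelopes, local structural identifiability analysis
    based on output-derivative Jacobian ranks, and a synthetic-data
    generator emulating functional magnetic resonance spectroscopy and
    imaging designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
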