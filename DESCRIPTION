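Package: cprsim
Title: Coupled Pneumatic-Actuator and Lumped-Parameter Circulation
    Simulation of Mechanical Chest Compression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the full mechanical cardiopulmonary resuscitation
    (CPR) chain: a valve-controlled pneumatic cylinder under PID depth
    control, a spring-damper sternal feedback model, and a 14-compartment
    lumped-parameter (RC-diode) model of the human blood circulation driven
    by chest-wall velocity through thoracic and pulmonary pressure sources.
    Generates square-wave compression instructions and noisy half-sine
    "manual" surrogate waveforms, computes perfusion metrics (cardiac
    output, coronary perfusion pressure, cerebral flow), and sweeps
    compression depth, frequency and duty cycle to locate hemodynamically
    optimal compression parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
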