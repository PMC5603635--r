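Package: ventrobust
Title: Robustness of Respiratory System Compliance Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates volume-controlled constant-flow ventilator breaths
    from a one-compartment respiratory model, computes gold-standard
    compliance by the interrupter technique, and benchmarks the robustness
    of two compliance monitors - a multilinear least-squares fit of the
    equation of motion and a 100-25-1 multilayer perceptron trained with
    resilient backpropagation - against graded random noise and transient
    sensor-disconnection faults injected into the airway-pressure channel.
    Degradation is quantified with per-level Bland-Altman bias and scatter
    tables and F tests comparing estimator precisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    nortest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
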