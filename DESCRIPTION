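Package: channelkit
Title: Kinetic Analysis of NMDA-Receptor Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative electrophysiology toolkit for NMDA-receptor variants:
    open-probability estimation from the kinetics of MK-801 open-channel block
    using a four-state D-R-O-B scheme, desensitization decomposition into onset
    and recovery rate constants, Hill fits of agonist concentration-response and
    steroid potentiation, Woodhull fits of voltage-dependent Mg2+ block,
    deactivation and charge-transfer metrics for synaptic-like responses, and
    half-amplitude idealization of single-channel records with dead-time
    censoring. A seeded synthetic-data module generates every input the
    pipeline consumes with known ground truth, so all estimators are validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    optparse,
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
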