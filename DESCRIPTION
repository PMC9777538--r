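Package: cranfis
Title: Cardiorenal Risk Modelling with an Adaptive Neuro-Fuzzy Inference
    System
Version: 0.1.0
Authors@R:
    person("cranfis", "maintainers", email = "cranfis@example.org",
           role = c("aut", "cre"))
Description: Predicts left-ventricular ejection fraction or cystatin-C
    based glomerular filtration rate from NT-proBNP, sodium and potassium
    with a 27-rule Takagi-Sugeno adaptive neuro-fuzzy inference system
    (ANFIS). Provides min-max normalization anchored to published cohort
    ranges, trapezoidal fuzzification over clinical reference bands,
    backpropagation and hybrid least-squares training, response-surface
    exports, risk-band classification, and a calibrated synthetic-cohort
    generator (truncated normal and lognormal moment matching) so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
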