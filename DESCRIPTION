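Package: toothEIS
Title: Impedance-Spectroscopy Classification of Early Tooth Demineralization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing early enamel demineralization from
    electrochemical impedance spectroscopy (EIS). Implements the forward
    model of a first-order equivalent circuit with a constant-phase
    element, complex non-linear least-squares (CNLS) fitting of measured
    spectra, a single-neuron classifier operating on the impedance phase
    at 15 Hz, a small multi-layer perceptron on fitted circuit
    parameters, a software emulation of a single-frequency sine-fit
    phase meter, binary-classification metrics (confusion matrix, ROC,
    AUC), and a synthetic-data generator so the whole pipeline can be
    exercised and validated without measured tooth data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
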