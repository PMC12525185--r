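Package: cwqsar
Title: Correlation-Weight QSAR Models from SMILES Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits quantitative structure-activity relationship (QSAR) models
    for continuous endpoints (such as pLC50, the decimal logarithm of acute
    aquatic toxicity in mg/L) directly from SMILES strings.  Molecules are
    tokenized into SMILES attributes (single SMILES atoms and adjacent-pair
    attributes); a Monte Carlo procedure optimizes one correlation weight per
    attribute so that the sum of weights over a molecule (the DCW descriptor)
    correlates with the endpoint; a one-variable least-squares calibration
    maps the descriptor to predictions.  Includes target functions with and
    without the index of ideality of correlation (IIC), a four-way random
    data split (active training, passive training, calibration, validation),
    an applicability domain based on statistical defects of attributes,
    validation statistics (R2, CCC, IIC, Q2, RMSE, MAE, F), multi-probe
    promoter interpretation, a synthetic-data generator with known linear
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
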