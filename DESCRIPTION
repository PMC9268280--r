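Package: podscreen
Title: Probability-of-Detection Validation for SERS Rapid Screening of
    Pesticide Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for threshold-based rapid screening of finite
    contaminants by surface-enhanced Raman spectroscopy (SERS) and for
    validating binary-output screening assays with the probability of
    detection (POD) model. Provides characteristic-peak libraries and
    qualitative calls from first-derivative peak detection, Gaussian
    intensity-threshold semi-quantitative classification against a
    maximum residue limit, POD curves with score-type 95% confidence
    intervals, POD differences (dPOD) for method and inter-laboratory
    consistency, limit-of-detection determination, and a synthetic SERS
    spectrum generator for end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
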