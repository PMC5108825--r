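Package: psaadjust
Title: Age- and BMI-Adjusted PSA Models for Prostate Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how age and body mass index (BMI) shift
    prostate-specific antigen (PSA) and whether adjusting PSA for them helps
    detect prostate cancer. Implements a multiplicative (log-linear) PSA
    model, the age/BMI adjustment equation, sensitivity and specificity at
    fixed and NICE age-banded thresholds, matched-specificity comparison of
    classifiers with McNemar's test, tenfold cross-validation, an
    above/below-threshold interaction test, and the arithmetic linking true
    and apparent test accuracy under incomplete biopsy verification. A
    calibrated synthetic case-control cohort generator makes the whole
    pipeline runnable and testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
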