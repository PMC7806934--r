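Package: stau2screen
Title: Lymphocyte STAU2 Immunofluorescence Screening Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification and evaluation pipeline for a lymphocyte-based
    breast-cancer screening test built on STAU2 immunofluorescence. Detects
    and measures fluorescent cell signals on multi-channel field images
    (perimeter and mean grey intensity filters, red/green colocalization,
    positivity calling), summarises each sample as an average fluorescence
    intensity and a percentage of marker-positive cells, evaluates two-axis
    quadrant cut-offs with the full screening-metric set (sensitivity,
    specificity, predictive values, odds ratio with Woolf confidence
    interval), computes Bayes post-test probabilities of disease, and tests
    cross-study differential-expression intersections for marker discovery.
    A synthetic-data module generates calibrated field images with ground
    truth, correlated two-group screening cohorts, and paired expression
    studies with planted shared signals, so the whole chain is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    pracma,
    stats,
    tiff,
    withr
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
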