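Package: irhisto
Title: Infrared Spectral Histopathology of Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for pixel-level tissue classification from FT-IR
    hyperspectral images of tissue-microarray biopsy cores: synthetic
    cohort generation with six pancreatic tissue classes, core-by-core
    Minimum Noise Fraction denoising, extraction of 123 band metrics
    (baseline-corrected integral, maximum and center of gravity per
    region, normalized to Amide I), patient-stratified splitting with
    class- and array-balanced sampling, random-forest classification
    ("digital staining"), and ROC/AUC evaluation at the pixel, core and
    patient level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    randomForest,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
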