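Package: duvmargin
Title: Patch-Based Classification and Decision Fusion for Deep-UV
    Fluorescence Margin Assessment
Version: 0.1.0
Authors@R:
    person("Margin", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for slide-level malignant/benign classification of
    deep-ultraviolet fluorescence whole-surface images.  A slide is tiled
    into non-overlapping 400x400 patches filtered by foreground fraction,
    patch features are extracted with a frozen convolutional backbone and
    classified with gradient-boosted decision trees, a Grad-CAM++ regional
    importance map weights each patch, and an importance-weighted count of
    malignant patches yields the slide decision.  Includes grouped
    stratified cross-validation with patient-level leakage control,
    ROC/AUC reporting, a synthetic phantom-slide generator with ground
    truth for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
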