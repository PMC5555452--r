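Package: modscreen
Title: Tumor-Index Scoring and Hit Calling for Dominant-Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for F1 dominant-modifier screens scored by
    melanotic tumor burden. Implements per-animal Tumor Index (TI) scoring on
    a quarter-abdominal-segment grid, batch-paired z-score normalization
    (NTI) against a parallel control cross, the 1-SD enhancer/suppressor
    classification rule, Monte-Carlo estimation of the rule's false-positive
    rate and power, and per-cell fluorescence quantification statistics
    (control-normalized intensity ratios, pooled-variance t tests, and
    EdU-positive plasmatocyte fractions). A synthetic-data generator with
    known ground truth makes the whole analysis testable without wet-lab
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
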