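Package: breathvoc
Title: Breath VOC Chromatogram Simulation, Peak Alignment and Asthma Phenotype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovery of volatile organic compound (VOC) biomarkers in
    exhaled breath analysed by portable gas chromatography. Simulates breath
    chromatograms with planted ground truth; preprocesses raw traces (asymmetric
    least squares baseline correction, Savitzky-Golay smoothing, peak detection
    and integration, total-area normalization, retention-time alignment) into a
    samples-by-peaks area matrix; selects discriminatory peak subsets by
    leave-one-out linear discriminant analysis accuracy with a decision-boundary
    margin tie-break; and performs two-step hierarchical classification of asthma
    and atopy phenotypes with PCA score-plot visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
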