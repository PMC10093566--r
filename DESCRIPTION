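Package: petln
Title: Quantitative FDG-PET Thoracic Lymph Node Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Node-level diagnostic-accuracy analysis of FDG-PET/CT for
    pre-operative thoracic lymph node staging in lung cancer. Provides
    VOI-based SUV quantification (SUVmax, SUVmean, EANM-style SUVpeak) with
    decay-corrected body-weight SUV normalisation, node-to-reference SUV
    ratios (primary tumour, liver, brainstem, contralateral lung), a
    quantified visual score and a five-condition multifactorial malignancy
    score, ROC analysis with DeLong or Hanley-McNeil confidence intervals
    and minimum-distance-to-(0,1) cut-off optimisation, full 2x2
    diagnostic-performance reporting, a calibrated synthetic cohort
    generator, and bundled reference results from a prospective 101-node
    staging cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
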