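Package: psmapercist
Title: PERCIST-Style Quantification and Response Prediction for PSMA PET
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of [68Ga]Ga-PSMA-11 PET volumes for
    response assessment after [177Lu]Lu-PSMA-617 radioligand therapy in
    metastatic castration-resistant prostate cancer. Provides blood-pool
    (aortic) referenced lesion segmentation with a PERCIST-style threshold,
    SUVpeak/SUVmax/volume metrics, patient-level tumor-burden summaries
    (PSMA-TV, TL-PSMA), imaging and biochemical response classification,
    ROC cutoff derivation with Youden and minimum-specificity rules and
    bootstrap optimism correction, accumulation-response linear mixed
    models with patient random intercepts, covariate-adjusted logistic
    screens with likelihood-ratio tests, and Kaplan-Meier/Cox survival
    analysis. Includes a synthetic phantom and cohort generator with known
    ground truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    lme4,
    RNifti,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
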