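Package: hierscore
Title: Interpretable Hierarchical Questionnaire Classification with Monte
    Carlo Dropout Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inherently interpretable hierarchical classifier for
    questionnaire-based mental-health treatment prediction. Item responses
    from standard screening instruments (PHQ-9, GAD-7, SIAS, PDSS, Fear
    Questionnaire, MANSA) are aggregated into learned "pseudosum scores"
    through non-negative weighted sums with a rectified-linear clamp, then
    combined with demographic features in a softmax output layer. Monte
    Carlo dropout yields predictive distributions for confidence and
    uncertainty; global and local explanations are read directly off the
    model weights. Ships a class-conditional synthetic cohort generator, a
    full evaluation-metric suite (balanced accuracy, weighted F1,
    one-vs-rest AUC, confusion matrices), violin-plot data extraction and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
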