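Package: bmicutpoints
Title: BMI Cut Points for Obesity-Related Comorbidity Incidence from
    Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate body mass index (BMI) thresholds ("cut
    points") beyond which the one-year incidence of obesity-related
    comorbidities can be accurately detected in electronic health record
    (EHR) data. Implements longitudinal cleaning of recorded heights and
    weights (absolute plausibility bounds plus per-patient dispersion
    rules and carry-forward/backward height imputation), cohort and
    index-visit construction with one-year look-back and follow-up
    windows, prevalent/incident case classification from ICD code sets,
    median (quantile) regression contrasts of baseline BMI between
    incident and non-incident patients, and receiver operating
    characteristic (ROC) cut-point estimation: the cut point is the
    observed BMI maximizing the Youden index, reported only when the
    area under the ROC curve exceeds a discrimination gate, with seeded
    bootstrap comparison of cut points between subgroups and between
    incidence- and prevalence-based definitions. A synthetic EHR
    generator with a known threshold ("step") disease model provides
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
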