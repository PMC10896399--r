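Package: ndpae
Title: Operationalizing and Validating Diagnostic Criteria for
    Neurobehavioral Disorder Associated with Prenatal Alcohol Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based operationalization of the ND-PAE (Neurobehavioral
    Disorder associated with Prenatal Alcohol Exposure) diagnostic criteria
    from multi-instrument neuropsychological scores, and the validation
    battery used to evaluate them. Scores from normed instruments (IQ-type
    standard scores, T-scores, scaled scores, z-scores, and binary
    diagnostic flags) are oriented and converted to a common z-scale, coded
    against impairment thresholds of 1.0, 1.5, and 2.0 standard deviations,
    and combined through the three-domain diagnostic logic (neurocognitive,
    self-regulation, adaptive functioning) under the original two-of-four
    and the modified one-criterion adaptive-functioning rules. Validation
    tools include endorsement tables, chi-square group contrasts,
    sensitivity/specificity/accuracy sweeps, Mann-Whitney AUC for binary
    predictors, logistic regression for age and sex effects, and binary-item
    psychometrics (Cronbach's alpha/KR-20, KMO, Bartlett's sphericity,
    principal components with Kaiser retention, Horn's parallel analysis,
    and promax rotation). A calibrated latent-factor cohort simulator
    generates synthetic data with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
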