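Package: prediabsim
Title: Markov Microsimulation of Pre-Diabetes Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Individual-level annual-cycle Markov model of glycemic disease
    progression (normal glucose tolerance, three pre-diabetes substates,
    type 2 diabetes, death) in Chinese adults, used to compare the
    cost-effectiveness of questionnaire-based (Chinese Diabetes Risk Score)
    pre-diabetes screening strategies against fasting-plasma-glucose
    screening at annual health examinations. Includes a typed parameter
    registry with age-band lookup and cumulative-to-annual probability
    conversion, a synthetic demography generator (truncated-normal ages,
    Gompertz-Makeham life table), screening cascades with OGTT confirmation,
    lifestyle-intervention cost accounting with discounting, incremental
    cost-effectiveness ratios against a willingness-to-pay threshold, and
    one-way, compliance-scan and probabilistic sensitivity analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
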