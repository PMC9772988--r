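Package: cgmrisk
Title: Time-in-Range Glycometrics and Distributional CGM Analysis for
    Type 2 Diabetes Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the 5-year risk of incident type 2 diabetes
    from continuous glucose monitoring (CGM) in people without diabetes.
    Computes consensus time-range glycometrics (time in range 70-140 mg/dL,
    time above 140 mg/dL, time below 70 mg/dL) from 5-minute interstitial
    glucose traces with wear-time quality filtering; represents each
    subject's glucose profile as a glucodensity and compares groups with
    2-Wasserstein distances, barycenters and a permutation test; applies
    ADA diagnostic and ATP-III metabolic-syndrome criteria, HOMA-IR and
    NGSP/IFCC HbA1c conversion; estimates cumulative incidence and exact
    (Garwood) Poisson incidence-rate intervals; and fits an adjusted
    logistic model for incident diabetes evaluated by ROC AUC (DeLong
    interval) and the Brier score. Includes a calibrated synthetic cohort
    and CGM trace generator for end-to-end testing and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
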