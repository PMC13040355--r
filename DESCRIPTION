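Package: scalpguard
Title: Bayesian Detection and Management of Appointment Scalping in
    Outpatient Registration Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates outpatient appointment registration event streams
    containing automated "scalper" behaviour, labels abnormal accounts with a
    two-of-three behavioural rule (cancelation bursts, device-to-card fan-out,
    sub-second operation speeds), summarises each account into a 12-variable
    behavioural feature vector, and scores accounts with a class-conditional
    Gaussian Bayes classifier whose prior is modulated in real time by a
    queuing model of patient flow. A graduated intervention layer (extra
    verification, SMS-style challenge-response, temporary booking restriction)
    closes the loop, and an evaluation module provides the contingency tests,
    effect sizes, risk ratios, interrupted time-series fits, bootstrap
    confidence intervals, confusion/ROC metrics and Equal Opportunity fairness
    summaries needed to assess a pre/post intervention experiment end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    lmtest,
    mvtnorm,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
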