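Package: ticonomics
Title: Cost-Utility Analysis of Aripiprazole Dosing in Paediatric Tic
    Disorders via YGTSS to EQ-5D-Y Utility Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-stage pharmacoeconomic analysis of oral
    aripiprazole in children and adolescents with tic disorders. Stage one
    maps Yale Global Tic Severity Scale (YGTSS) scores onto EQ-5D-Y health
    utilities with Gaussian-identity linear models and logit-link beta
    regression, with AIC/BIC/adjusted R-squared model comparison and
    MAE/RMSE validation. Stage two evaluates a 52-week decision tree
    comparing high-dose and low-dose oral aripiprazole (expected costs,
    QALYs, responder counts, ICER, net monetary benefit) with one-way
    (tornado) and probabilistic sensitivity analysis, cost-effectiveness
    acceptability curves, and incremental cost-effectiveness scatter
    exports. A synthetic-cohort generator reproduces the statistical
    structure of the survey data the mapping stage assumes, so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
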