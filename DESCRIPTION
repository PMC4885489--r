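Package: cypind
Title: Dynamic Prediction of CYP3A4 Induction Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting drug-drug interactions (DDIs) that arise
    from induction of CYP3A4. Fits sigmoidal Emax concentration-response
    models to fold-induction data from human hepatocyte donors, calibrates
    in vitro induction parameters against in vivo rifampicin reference
    values (IVIVE), simulates victim and perpetrator pharmacokinetics with
    a minimal PBPK model in which active CYP3A4 amounts in liver and gut
    follow enzyme-turnover dynamics, replicates clinical DDI study designs
    in virtual trials with population variability, and scores predicted
    AUC ratios against observations with geometric mean fold error, RMSE
    and observation-scaled acceptance limits. Bundles transcriptions of
    published rifampicin and other-inducer DDI study summaries as plain
    text fixtures, plus synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
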