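Package: fallrisk
Title: Fall-Risk Assessment for Older Adults from Literature Odds Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts published odds ratios for fall-risk factors in
    community-dwelling adults aged 65 and over into per-factor probability
    contributions, combines them under a noisy-OR causal-independence model,
    marginalizes unknown exposures through factor prevalences, and calibrates
    the baseline risk term against a target annual faller incidence by
    bisection. The compiled model can be exported as an equivalent
    probabilistic logic program with annotated disjunctions (LPAD) in
    cplint-style syntax. Includes a synthetic-cohort simulator matching the
    model's generative assumptions and a validation battery (ROC/AUC with
    DeLong or bootstrap confidence intervals, Brier score, Hosmer-Lemeshow
    test, decile calibration table), plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
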