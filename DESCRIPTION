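Package: netbenefit
Title: Decision Curve Analysis with Overall Net Benefit, ROC Linkage, and
    Case-Control Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates clinical prediction models and binary diagnostic
    tests by their net benefit across threshold probabilities.  Implements
    the net benefit for the treated, the net benefit for the untreated,
    and their sum, the overall net benefit, together with the reference
    strategies of treating none, treating all, and a hypothetical perfect
    model.  Links decision curves to ROC analysis (Youden-index versus
    net-benefit-optimal cutoffs, sensitivity/specificity forms of the net
    benefit, decision curves of dichotomized models) and extends decision
    curve analysis to case-control designs via prevalence-adjusted
    predicted probabilities and prevalence sweeps.  Includes a synthetic
    cohort generator for simulation studies and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
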