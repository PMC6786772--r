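Package: subpred
Title: Model-Based Prediction of Finite-Population Totals Under Non-Ignorable Non-Response
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Prediction (model-based) estimation of a finite-population total when unit
    non-response is non-ignorable, i.e. when respondents and non-respondents follow
    different linear superpopulation models. Implements the respondent-only predictor,
    the Hansen-Hurwitz-type sub-sampling predictor that combines separate regime fits
    from the first call and a second-call sub-sample of non-respondents, and partially
    ridge regression (PRR) and weighted-least-squares variants for super-collinear or
    heteroscedastic regimes. Provides the closed-form model bias/variance/MSE of the
    predictors, an admissible ridge-tuning range, synthetic population generators,
    and bootstrap and Monte-Carlo evaluation protocols reporting (relative) bias and
    (relative) mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
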