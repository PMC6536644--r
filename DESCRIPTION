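Package: dtmbc
Title: Decision-Theoretic Modelling of Health Behavior Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting behavioral intentions and behavior
    probabilities under three models of health behavior change: expected
    utility theory (EUT), the Theory of Planned Behavior (TPB), and a
    decision-theoretic model (DTM) that embeds subjective norm and
    self-efficacy into an intention-action-state expected-utility chain.
    Includes Likert questionnaire scoring to model parameters,
    maximum-likelihood estimation of decision parameters from binary
    intention data with TPB-vs-DTM model comparison, seeded simulation of
    heterogeneous agent cohorts with Bernoulli intention, action and
    outcome draws, worked scenarios contrasting the models, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
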