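Package: hbmscore
Title: Second-Order Confirmatory Factor Analysis and Weighted Scoring for
    Health Belief Model Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating injury-prevention health-education
    programmes with the Health Belief Model (HBM). Fits a second-order
    confirmatory factor model (five first-order constructs -- perceived
    susceptibility, seriousness, benefits, barriers and cues to action --
    driven by one latent health-belief factor, with a structural
    barriers-to-cues path) to 22-item Likert questionnaire data by normal
    theory maximum likelihood; reports standardized solutions, total
    effects, chi-square and the RMSEA/GFI/AGFI/NFI/CFI/IFI fit battery
    with an RMSEA confidence interval. Provides CFA-weighted (CFAWS) and
    simple-sum (SSS) health-belief scoring, Cronbach's alpha reliability,
    pre/post cohort comparison by two-sample t-tests, a latent-model
    simulator for 5-point ordinal item responses, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
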