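Package: calfplanr
Title: Energy-Allowable Growth Simulation and Feeding-Plan Evaluation for
    Preweaning Dairy Calves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A daily time-step bioenergetic simulator for preweaning and
    weaning dairy calves. Predicts starter (solid feed) intake under
    temperate and semitropical conditions, models digestibility maturation
    of starter nutrients as a function of cumulative non-fibrous
    carbohydrate intake, converts metabolizable energy above maintenance
    into energy-allowable daily gain, and compares up to four milk
    allowance plans on growth and feed-cost key performance indicators.
    Includes an observed-versus-predicted assessment module (mixed-model
    regression with random study effects, RMSE, R-squared, Lin's
    concordance correlation, intraclass correlation) and a synthetic
    multi-study dataset generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
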