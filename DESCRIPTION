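Package: slcurves
Title: Statistical-Learning Curves from Alternating Serial Reaction Time Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for implicit statistical learning
    measured with the alternating serial reaction time (ASRT) task. Generates
    ASRT sessions with counterbalanced pattern permutations and simulated
    responses under a known exponential learning curve, labels trials by the
    triplet taxonomy (Pattern-High, Random-High, Random-Low), computes
    per-block statistical-learning (SL) scores, fits exponential, power and
    linear learning models by bounded maximum likelihood and compares them with
    AICc, BIC and BIC-approximated Bayes factors, extracts each participant's
    learning potential (saturation A) and efficiency (time constant tau), and
    correlates them with executive-function test scores using Kendall's tau-b.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
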