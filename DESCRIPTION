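Package: socialdining
Title: Group-Formation Inference for Social Predation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical inference for group formation in predation assays,
    built around two seating models for predators aggregating on prey: a
    uniform-choice null model in which each predator selects a prey item
    independently with equal probability, and a "social dining model" (a
    Chinese restaurant process over a finite set of prey) whose concentration
    parameter measures the propensity to join an occupied prey item.
    Provides Monte-Carlo tail probabilities for observed group-size
    statistics, moment-matching estimation of the concentration parameter by
    bisection with common random numbers, exact enumeration oracles for both
    models, exact binomial choice-assay tests with Clopper-Pearson or
    Jeffreys intervals, Welch and Wilcoxon comparisons, synthetic data
    generators with known ground truth, and a one-shot reproduction report
    for the packaged feeding-trial and choice-assay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
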