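Package: ruleglass
Title: Rule-Based Explanations and Tailored Interventions for Clinical Risk Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines class-based association rules from tabular cohort data with the
    Apriori algorithm under five control parameters (top-ranked features, maximum
    left-hand-side length, minimum commonality, minimum confidence, and a
    confidence-difference tolerance for subsumption pruning), prunes the rule set,
    and uses the surviving rules to explain any risk model's positive predictions
    and attach expert-curated interventions from a knowledge base. Includes
    entropy/MDL supervised discretization of continuous features, a five-factor
    iterative rule-ranking scheme, explanation-coverage metrics, and a synthetic
    cohort generator with planted rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
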