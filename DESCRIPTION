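Package: homgroups
Title: Latent Interpretive Groups in Plural Definite Homogeneity Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing truth-value and ternary-reward judgment data on
    plural definite descriptions ("the trucks are blue") in mixed ("gap")
    situations, where homogeneity makes both the positive sentence and its
    negation neither true nor false. The package derives predicted response
    templates for interpretive groups (existential, homogeneous, universal and
    wide-scope/strategy readings, with or without scalar implicatures) from a
    finite-model trivalent semantics with recursive exhaustification; simulates
    cohorts of subjects with known latent groups and lapse noise over binary
    and ternary judgment designs; implements rule-based subject categorization,
    inclusion criteria, response-bias flags and chi-square comparisons of group
    distributions; computes exact tail probabilities that an observed group
    configuration arose from random responders; and fits a Bayesian
    latent-group finite-mixture response model (Bernoulli-logit for binary
    judgments, cumulative-logit for ternary rewards) with per-subject posterior
    group probabilities and leave-one-out (elpd) comparison across group
    inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
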