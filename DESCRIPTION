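Package: ftrk
Title: Future-Tense Elicitation Scoring, Hyperbolic Discounting, and
    Bayesian Moderated Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how grammatical future-time reference relates
    to temporal discounting in two-language cohorts (English and Dutch).
    Provides a deterministic closed-vocabulary classifier for elicited
    future-/present-tense sentences with modal dominance, estimation of
    per-participant hyperbolic discount rates k from binary intertemporal
    choices by enumeration of indifference points with geometric-mean tie
    resolution, a flat-prior Bayesian moderated mediation model with
    conditional and counterfactual indirect effects, posterior sign
    probabilities and Bayesian R-squared, and a synthetic-cohort generator
    so the complete pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
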