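Package: hgfsrt
Title: Categorical State-Transition Hierarchical Gaussian Filter for the
    Probabilistic Serial Reaction Time Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the four-choice probabilistic serial reaction time
    (SRT) task with a mid-experiment probability reversal, filters the
    resulting stimulus streams with a categorical state-transition
    hierarchical Gaussian filter (HGF) that tracks Gaussian beliefs about
    the log-odds of all sixteen category-to-category transitions, derives
    trial-wise belief regressors (Shannon surprise, expected and unexpected
    uncertainty), maps them onto log reaction times through a linear
    Gaussian response model, and fits the eight free parameters per
    participant by Markov chain Monte Carlo with Gelman-Rubin and effective
    sample size diagnostics.  Parameter-recovery studies on simulated
    cohorts close the loop from simulation to inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
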