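Package: chaser
Title: Cognitive Hierarchy Modelling of Adaptive Mentalization in Repeated Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling adaptive mentalization in repeated
    rock-paper-scissors-style games. Implements the CHASE model (cognitive
    hierarchy with Bayesian belief updating over the opponent's depth of
    recursive reasoning), five competitor learning models (reinforcement
    learning, fictitious play, experience-weighted attraction, self-tuning
    EWA, and a confidence-based theory-of-mind model), fixed-level
    artificial opponents, maximum-likelihood fitting with AIC, random-effects
    Bayesian model selection (exceedance and protected exceedance
    probabilities), parameter- and model-recovery harnesses, posterior
    predictive checks, trial-level strategy assignment, and export of
    trial-wise model-derived regressors (choice value, action prediction
    error, belief update).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
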