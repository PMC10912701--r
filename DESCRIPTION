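Package: redirkick
Title: Bayesian Adaptive Training Simulation for Penalty-Kick Redirection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates adaptive penalty-kick redirection training against a
    virtual goalkeeper and estimates each player's 50% redirection threshold,
    the minimum goalkeeper-dive lead time at which a kick is successfully
    redirected half the time. Provides a psychometric observer model with
    lapse and anticipation behaviour, synthetic run-up kinematics with a
    monotone time/radius mapping that triggers the goalkeeper dive at a
    commanded lead time, a grid Bayesian engine that updates a posterior over
    psychometric parameters after every kick and adaptively selects the next
    dive lead time, a campaign orchestrator reproducing the 20-kick session
    design, and analytics for threshold change, posterior probability of
    improvement, success-rate curves and the exact two-tailed binomial test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
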