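Package: bidlearn
Title: Adaptive Learning Models of Repeated Double-Auction Bidding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, maximum-likelihood fitting and model comparison of
    adaptive learning models of buyer behaviour in repeated double-auction
    markets. Implements the bidding task environment (three market types,
    a 101-point bid grid, a lottery entry stage and truncated-Gaussian
    opponent pools), six learning agents spanning model-free and
    counterfactual reinforcement learning and directional-learning families,
    aggregated (fixed-effects) and per-subject (random-effects) likelihood
    fitting with basin-hopping bounded quasi-Newton optimization and BIC
    ranking, forced-choice model enactment yielding trial-level learning
    signals (preferred-bid value, directional signature, pseudo reward
    prediction error), and the behavioural statistics used to characterise
    bidding: transaction rates, market discrimination, directional-learning
    compliance, bid-increment distributions, trend slopes and
    posterior-predictive checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    e1071,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
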