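Package: farmersgame
Title: Spatial Iterated Prisoner's Dilemma with Wealth Accumulation and a
    Survival Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the Farmer's Game, an iterated
    Prisoner's Dilemma played on a square lattice in which players accumulate
    wealth, pay a consumption cost per interaction, and die (are removed and
    their neighbours reconnected) when wealth drops to zero or below.
    Implements tit-for-tat with forgiveness and four wealth-conditional
    variants, Monte Carlo replication, survival and wealth summaries, and a
    bisection search for the wealth-equilibrium cost per turn.  A companion
    reconciliation pipeline maps monetary stakes to a wealth-relative
    temptation parameter, predicts cooperator density from
    temptation-response curves, and correlates predictions against observed
    public-goods contribution fractions across countries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
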