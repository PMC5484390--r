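Package: lcanet
Title: Leaky Competitive Accumulator Networks for Multi-Attribute Choice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-layer leaky competitive accumulator model of multi-attribute
    preferential choice. Recurrent attribute sublayers transform raw attribute
    values (identity, identify-best, identify-worst, or normalization regimes)
    before a threshold-based preference accumulation layer turns stochastically
    sampled attribute information into choices and decision times. Provides
    parameter presets under which the network mimics classic heuristic choice
    rules (lexicographic, CONF, weighted pros, majority of confirming
    dimensions, equal weights, weighted additive, and rank-based variants),
    idealized symbolic oracles for those rules, region maps of sublayer
    transform regimes over the self-feedback/inhibition plane, and Monte-Carlo
    simulation studies of heuristic identification and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
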