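Package: notowave
Title: Stochastic G1/S Transition Waves in the Developing Notochord
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of the stochastic G1/S transition in the
    developing zebrafish notochord from dual-channel Fucci live-imaging
    traces. Implements transition calling from red/green intensity traces,
    spatial scoring of the G1/S transition window (posterior-most green
    cell, anterior-most red cell, window green counts and green-pair
    counts), Monte-Carlo linkage nulls for independence of S-phase entry
    between cell columns, a Markov lattice model of a travelling regulatory
    wave with continuous and periodic step modes, estimation of the
    per-frame transition probability from paired waiting-time differences
    via the closed-form difference-of-geometrics distribution, and
    Kullback-Leibler model selection among candidate wave periodicities.
    A synthetic-data generator reproduces the statistical structure of the
    imaging data so the whole pipeline is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
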