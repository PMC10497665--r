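Package: nudgenet
Title: Nudged Cooperation in an Experimental Communication Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of a repeated question-and-expert
    communication game on a 25-player network, in which players pay to send
    inquiries and replies and are rewarded for locating the one player whose
    expertise matches their question. Implements the exact round mechanics
    (assignment drawing, reply legality, reward attribution), the 6-regular
    diameter-two suggestion graph used as a nudge, an exact expected-profit
    model over random directed inquiry networks under a reply-rate assumption,
    a calibrated synthetic session generator, and the behavioral metrics used
    to analyse sessions: reply share, relative return on investment along
    links, suggested and bi-directional link decomposition, a reciprocity null
    model, and standard rank-based session comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
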