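Package: ircmech
Title: Mechanistic Analysis of Enzymatic Group-Transfer Reaction Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the mechanism of enzymatic phosphoryl-transfer (and
    general group-transfer) reactions from reaction-path data: multi-frame XYZ
    geometries with energies along an intrinsic reaction coordinate, per-frame
    Wiberg bond orders, and natural-population-analysis atomic charges.
    Provides stationary-point detection on the potential-energy profile,
    associative/dissociative transition-state classification via Pauling's
    bond order-distance relation, bond-order-derivative synchronicity analysis
    (bond events, crossings, pairwise offsets), fragment charge-evolution
    reports, per-frame geometric measurements (distances, angles, metal
    coordination, hydrogen bonds), and a deterministic synthetic-path
    generator with known ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    yaml,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
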