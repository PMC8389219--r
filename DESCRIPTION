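Package: antioxkin
Title: Transition-State Kinetics, Spin-Crossing Analysis, and Energetics for
    Antioxidant Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of quantum-chemistry thermochemistry tables
    for phenolic antioxidant chemistry, without any electronic-structure
    computation. Computes Eyring transition-state-theory rate constants with
    asymmetric-Eckart tunneling corrections, branching ratios and overall rate
    constants for competing reaction pathways, and water-assisted
    tautomerization barrier series. Locates singlet/triplet crossings along
    one-dimensional reaction-coordinate scans, refines minimum-energy crossing
    points (MECP) on model surfaces with an effective-gradient optimizer, and
    classifies their kinetic relevance. Also provides closed-form polyprotic
    acid speciation at a given pH, reaction Gibbs-free-energy bookkeeping for
    metal-chelation equilibria, and inhibition constants derived from docking
    binding-energy decompositions. Synthetic-data generators with embedded
    ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
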