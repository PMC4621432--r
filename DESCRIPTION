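Package: quadfly
Title: Four-Quadrant Olfactometer Behavior and Olfactory Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies free-walking fly behavior in a star-shaped four-quadrant
    olfactometer and the accompanying olfactory electrophysiology. Provides arena
    geometry with 90-degree rotation semantics, blob detection and track linking
    with the intersection-terminates-tracks rule, the Attraction Index (AI) and
    its time course, four-quadrant and 3-well egg-laying quantification via the
    Oviposition Preference Index (OPI), windowed solvent-corrected single-sensillum
    spike responses and electroantennogram peak deflections, and an agent-based
    synthetic-data generator (correlated random walks biased by an odor quadrant
    or a deposited pheromone field with first-order evaporation, egg laying,
    Poisson spike trains, EAG-like traces, rendered infrared-style frames) so the
    whole pipeline is testable with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
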