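Package: gqmech
Title: Mechanical Unfolding Analysis of Tetrameric Parallel G-Quadruplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of mechanical (constant-velocity pulling)
    unfolding of tetramolecular parallel G-quadruplex stems. Computes
    quartet-plane geometry from trajectory frames (SVD best-fit planes,
    planarity, tilt, rise, helical twist), reconstructs and decomposes the
    pulling force from a moving harmonic restraint (out-of-plane angle,
    horizontal and vertical components, force-edge overlap, rupture and
    transition-inducing forces), tracks quartet hydrogen bonding to classify
    unfolding events (unzipping, strand slippage, opening, detachment, spiral
    intermediates, rotation, refolding), and measures channel cation
    occupancy. Includes a synthetic-trajectory generator producing ideal
    parallel all-anti G-stems, scripted deformations and unfolding pathways,
    and harmonic force traces with complete ground-truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
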