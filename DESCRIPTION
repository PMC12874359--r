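Package: fsmpath
Title: Freezing String Method for Transition-State Guess Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates transition-state guess structures and approximate
    reaction pathways between two molecular geometries with the freezing
    string method (FSM). Two strings are grown inward from the reactant and
    product; each newly placed frontier node is optimized perpendicular to
    the pathway tangent and then frozen, and the highest-energy node of the
    joined string is the transition-state guess. Interpolation between
    frontier nodes is performed either by linear interpolation in redundant
    internal coordinates (bonds, angles, linear bends, torsions,
    out-of-plane angles) with Wilson B-matrix back-transformation to
    Cartesians, or by linear synchronous transit (LST) least-squares
    interpolation in internuclear distances. Energies and gradients come
    from pluggable calculators: the analytic Mueller-Brown surface, a toy
    molecular force field, or a file-based adapter around an external
    electronic-structure program, so the full algorithm is testable without
    quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
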