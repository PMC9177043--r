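Package: multipmd
Title: Multiple-Walker Multiple-Path Metadynamics on Model Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Engine for free-energy calculations along adaptive cyclic path
    collective variables, modeled on the protocol used to resolve inside and
    outside Watson-Crick-Franklin to Hoogsteen base-pairing transitions.
    Provides cyclic path curves with progress/distance projection and
    fading-memory node updates, shared-bias multiple-walker metadynamics with
    tube and attractor restraints, overdamped Langevin dynamics on analytic
    two-channel model landscapes with quadrature and string-method reference
    oracles, free-energy profile reconstruction with direction-resolved
    barrier extraction and diffusion diagnostics, and calculators for the DNA
    structural collective variables (glycosidic and base-rolling
    pseudo-dihedrals, base-opening angle, pairing distances, hydration
    counts) from PDB coordinates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
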