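Package: pbmem
Title: Finite-Element Poisson-Boltzmann Electrostatics for Membrane Channel Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A linear-tetrahedral finite-element solver for the Poisson-Boltzmann
    equation in implicit-solvent models of membrane channel proteins. Supports an
    implicit membrane slab with automatic recognition of the water-filled channel
    (pore) region, lateral (x/y) periodic boundary conditions realized by
    degree-of-freedom identification across opposite box faces, several numerical
    treatments of the singular fixed point charges (direct delta integration,
    vertex-on-charge, average and barycentric-weighted nodal assignment), a
    singular/harmonic/regular potential decomposition solver for cross-validation,
    and electrostatic plus SASA-based non-polar solvation energy reporting.
    Includes synthetic generators for concentric-sphere Born-ion meshes and
    periodic-box toy channel systems, and TetGen-style node/ele/face, PQR and
    legacy VTK input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
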