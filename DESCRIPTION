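Package: depchip
Title: Simulation of Dielectrophoretic Cell Separation in a Two-Stage
    Lab-on-Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finite-element simulation pipeline for a planar two-stage
    Y-channel lab-on-chip that separates circulating tumor cells (CTCs),
    white blood cells (WBCs) and platelets (PLTs) by negative
    dielectrophoresis. Builds the parametric device geometry with
    protruding electrodes, generates tagged triangular meshes, solves
    steady creeping (Stokes) flow and the quasi-static electric potential,
    evaluates the single-shell Clausius-Mossotti model and the
    dielectrophoretic force, traces cell trajectories under drag and DEP,
    and reports separation efficiency, outlet purity and throughput,
    including the parametric design sweep and grid-convergence study used
    to select an optimal device.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
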