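Package: betashape
Title: Shape-Theory Analysis of Betalain Antioxidants
Version: 0.1.0
Authors@R:
    person("betashape", "maintainers", email = "betashape@example.org",
           role = c("aut", "cre"))
Description: Riemannian shape distances between optimized molecular
    geometries and their deprotonated anions (globally and restricted to
    per-element subspaces), thermodynamic-cycle antioxidant descriptors
    (BDE, PA, ETE, IP, PDE) with radical-scavenging mechanism
    classification (HAT, SPLET, SET-PT), and a similarity-invariant
    canonical ligand orientation with a ten-member rotation ensemble for
    molecular-docking preparation.  Includes readers and writers for XYZ,
    PDB, SDF (V2000) and PDBQT coordinate files, a synthetic-fixture
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
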