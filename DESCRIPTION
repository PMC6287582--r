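Package: rinmd
Title: Residue Interaction Networks from Protein Structures and Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives residue interaction networks (RINs) from static protein
    structures (PDB) and molecular dynamics trajectories (CHARMM/NAMD PSF and
    DCD files). Detects nine classes of residue-residue interactions with
    explicit geometric and energetic criteria (C-alpha contacts, hydrogen
    bonds, salt bridges, disulfide bridges, cation-pi, pi-pi,
    arginine-arginine pairing, Coulomb and Lennard-Jones contacts),
    aggregates per-frame interaction multigraphs into a consensus network
    with per-edge persistence, computes node centralities, and builds
    per-interaction-type Pearson correlation matrices describing coordinated
    formation and rupture of interactions over time. Includes a synthetic
    fixture generator that plants interactions with exactly known geometry
    and correlation structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
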