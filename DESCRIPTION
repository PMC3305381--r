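Package: allodyn
Title: Trajectory-Ensemble Analysis of Allosteric Coupling in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying allosteric communication from
    conformational ensembles of a protein backbone: normalized
    cross-correlation maps of Cartesian and dihedral-angle fluctuations,
    Kabsch superposition, RMSD/RMSF profiles with automatic equilibration
    detection, radius-bounded k-means clustering of merged labeled
    ensembles with population-overlap reports, and a Gaussian network
    model based synthetic-ensemble generator with analytically known
    correlation structure for validation. Designed around the
    KIX/MLL/c-Myb allosteric system but applicable to any single-chain
    backbone ensemble supplied as multi-model PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
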