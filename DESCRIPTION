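Package: porescape
Title: Pore Profiling, Hydrophobicity Mapping and Gating Analytics for Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based pore detection and dot-surface mapping of ion-channel
    conduction pathways over structures and molecular-dynamics trajectories.
    Computes per-slab pore radius, center and hydrophobicity profiles from a
    dot Connolly surface, Molecular Hydrophobicity Potential (MHP) fields and
    area-weighted surface-MHP distributions, cylindrical (angle by elevation)
    and dynamic (time by elevation) pore maps, atomic-solvation-parameter
    (ASP by ASA) residue solvation energetics with a methylene-equivalent
    heat-capacity estimator, linear-mutual-information generalized
    correlations of residue motions, and gate-geometry metrics (quadrilateral
    areas, pore-axis distances, helix bend angles).  Ships a synthetic-data
    generator producing four-fold symmetric channel models, alkane model
    compounds and trajectories with known ground truth, so the whole pipeline
    is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
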