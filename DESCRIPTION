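Package: phosnap
Title: Geometric and Kinetic Analysis of Enzymatic Phosphoryl-Transfer Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing nucleophilic attack at phosphorus in
    enzyme active sites from series of crystallographic snapshots, developed
    around the dUTPase-catalyzed hydrolysis of dUTP at the alpha-phosphate.
    Reads and writes PDB coordinate files, perceives covalent bonds from
    covalent radii, detects near-attack conformations (a water nucleophile
    in-line with the scissile bond), surveys non-bonded P-O contact distances
    against van der Waals criteria, quantifies Walden inversion at a
    tetrahedral phosphorus via signed volumes, measures rotations about bond
    axes and per-atom/side-chain displacements between snapshots, scores
    five-coordinate phosphorus geometry against the ideal trigonal-bipyramidal
    transition state of the associative A_N D_N mechanism, computes the Q1/Q2
    bond-breaking/bond-forming reaction coordinates, builds linear morph
    trajectories across snapshot series, simulates first-order 31P-NMR
    multiplet spectra, and fits multi-peak intensity time courses globally
    with a single shared first-order rate constant. A seeded synthetic-data
    generator provides ground-truth fixtures for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
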