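Package: mdpost
Title: Comparative Post-Processing of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and two-system comparison of molecular dynamics
    trajectories of protein complexes: rigid-body superposition and
    deviation/fluctuation metrics (RMSD, RMSF), dynamic cross-correlation
    matrices of C-alpha fluctuations, essential dynamics (Cartesian principal
    component analysis, shared-subspace projection, RMSIP and overlap
    matrices, porcupine modes, free-energy landscapes, k-means representative
    conformations), geometric interaction analysis (contacts, hydrogen bonds,
    salt bridges, hydrophobic contacts, occupancies, Shrake-Rupley solvent
    accessible surface area and interface-area distributions), implicit
    solvent binding free energies with per-residue decomposition
    (molecular-mechanics terms plus a generalized-Born polar and linear
    nonpolar solvation model), and correlation-weighted residue interaction
    networks with Girvan-Newman community detection.  A synthetic two-chain
    complex and trajectory generator with fully known planted statistical
    structure supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
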