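Package: chpi
Title: CH-pi Interaction Detection and Scoring for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CH-pi contacts between aliphatic C-H groups and aromatic
    rings in protein-ligand structures, computes their geometric descriptors
    (H-centroid distance, theta, omega, theta1, theta2, horizontal and
    vertical offsets), and scores them with an empirical pairwise CH-pi
    energy term added to a re-implemented AutoDock Vina-style base score.
    Includes hydrogen-dependent and hydrogen-independent functional forms,
    idealized methane-benzene dimer builders and energy scans, a two-stage
    grid-search protocol that re-derives the CH-pi parameters from reference
    dimer energy curves, and a torsion grid-search pose optimizer with clash
    filtering. Reads PDB and PDBQT files, places missing aliphatic
    hydrogens, and ships a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
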