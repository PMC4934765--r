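Package: basereadout
Title: Energetic and Geometric Analysis of Direct DNA Base Readout by
    Amino-Acid Side Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers sequence-specific DNA base-readout motifs from
    structures of protein-DNA complexes.  Extracts interacting amino
    acid-nucleotide dimers by a van der Waals distance criterion, superposes
    them into a common base frame, clusters the side-chain poses by greedy
    reference-atom RMSD clustering, scores each dimer with an Amber-form
    molecular-mechanics interaction energy (supermolecular approach with
    monomer deformation terms, hydrogen-only conjugate-gradient relaxation,
    optional generalized-Born/surface-area implicit solvation at several
    dielectric constants), and grades every amino acid-base-edge combination
    against four criteria of specificity built on Freedman-Diaconis
    interaction-energy profiles.  Includes a synthetic-data module that
    writes PDB fixtures with an idealized B-DNA duplex, planted canonical
    binding motifs and controlled-identity protein sequence families, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
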