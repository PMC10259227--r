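Package: ppisite
Title: Energy-Grid and Propensity-Based Prediction of Protein-Protein
    Interaction Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interaction sites on a protein surface
    by combining a cubic-lattice methyl-probe van der Waals energy map with
    per-atom residue interface propensity, hydrophobicity, and solvation
    free-energy scores. Interfaces of experimentally determined complexes are
    demarcated as atomic contact pairs (inter-chain atoms closer than the sum
    of their van der Waals radii plus a tolerance), favorable grid points are
    clustered into candidate sites, candidate sites are filtered by learned
    score domains and ranked, and predictions are evaluated against actual
    interfaces with a combined precision/coverage overlap score. Includes a
    deterministic generator of synthetic two-chain complexes with a known
    interface for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
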