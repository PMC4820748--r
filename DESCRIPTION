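Package: membanchor
Title: Membrane-Association Analysis for Coarse-Grained Protein-Bilayer
    Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how a lipid-anchored peripheral membrane
    protein associates with a bilayer in ensembles of coarse-grained
    molecular dynamics trajectories. Reads multi-model GRO and a simple
    whitespace XYZ trajectory dialect, detects snapshot-level
    protein-membrane contacts from minimum-image minimum distances,
    identifies irreversible lipid-anchor insertion events as sustained
    anchor-residue contact runs, builds ensemble cumulative and windowed
    ("subtotal") association curves, and maps per-residue lipid head-group
    contact probabilities onto structures via the PDB B-factor column.
    Includes a seeded Brownian-dynamics rigid-body generator of synthetic
    protein-near-membrane ensembles with ground-truth event logs for
    validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
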