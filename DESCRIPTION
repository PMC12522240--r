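Package: sigenum
Title: Deterministic Enumeration of Molecules from Counted
    Extended-Connectivity Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reverse-engineers molecular structures from counted
    extended-connectivity fingerprints (ECFP). An alphabet linking
    canonical atomic signatures to the Morgan bits they generate is
    harvested from a molecule collection; a query fingerprint is then
    inverted by solving the linear Diophantine system formed by the
    per-bit partition equations under bond-consistency and graphicality
    constraints, using integer partitions and orbit decomposition.
    Surviving molecular signatures are turned into molecular graphs by a
    constraint-driven backtracking reconstruction, expanded into
    stereoisomers, and filtered to exact fingerprint matches. Standard
    cheminformatics steps (SMILES parsing, canonicalization, Morgan
    fingerprints with per-atom bit provenance, stereoisomer enumeration)
    are delegated to the RDKit toolkit through a bundled batch bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdkit package, available
    on the PATH as 'python' (or set via options(sigenum.python = ...))
Config/testthat/edition: 3
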