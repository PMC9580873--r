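Package: coevnet
Title: Weakly Co-Evolving Residue Networks from Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identity-level co-evolution statistics for protein multiple
    sequence alignments: per-column residue profiles, the residual between
    observed and expected joint residue frequencies at position pairs with
    Fisher-exact significance, and threshold-filtered co-evolution networks.
    Networks are rendered as a cylindrical radial node-link layout with a
    seeded column-order randomization control, and selected residue pairs are
    validated against a protein structure via an expected-distance baseline
    computed per sequential separation. Includes generators for synthetic
    alignments with planted identity-pair couplings of controlled residual
    strength and for toy backbones (ideal helix, random chain) with known
    distance geometry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
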