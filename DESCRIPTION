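Package: hvnlr
Title: Phylogenetic Partitioning and Entropy-Based Binding-Site Prediction
    for Plant NLR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraspecies diversity of plant
    Nucleotide-binding Leucine-Rich Repeat (NLR) immune receptors across a
    pan-genome. Partitions a bootstrapped NB-ARC phylogeny into near-allelic
    clades of bounded size and maximal support, iteratively refines clades by
    branch-length, bootstrap and ecotype-overlap rules, profiles per-column
    Shannon entropy and hydrophobicity of clade alignments to detect highly
    variable NLR (hvNLR) clades, maps high-entropy residues onto a 2D
    representation of the leucine-rich repeat (LxxLxLxx) concave surface, and
    scores entropy-based binding-site predictions against receptor-ligand
    contacts derived from a complex structure. Includes a seeded synthetic
    pan-NLRome generator with machine-readable ground truth, and writers for
    UCSF Chimera attribute files and iTOL dataset annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'hvnlr-package.R'
    'classes.R'
    'diversity.R'
    'io.R'
    'lrr.R'
    'partition.R'
    'pipeline.R'
    'simulate.R'
    'structure.R'
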