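Package: adgrevo
Title: Phylogenetic Classification, Numbering, and Selection Analysis of
    Adhesion GPCRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the evolutionary analysis and hierarchical
    classification of vertebrate adhesion G protein-coupled receptors
    (aGPCRs) and secretin-like receptors from aligned seven-transmembrane
    (7TM) domain sequences. Implements Poisson-corrected amino-acid
    distances with pairwise deletion, neighbor-joining tree construction
    with bootstrap bipartition support and outgroup rooting, TM-fragment
    phylogenies, the level-based ADGR nomenclature (family letters, genus
    numbers, species-private subtype letters, splice-variant labels),
    fish-mammal one-to-one orthology detection and presence matrices, a
    conservation-based generic X.50 residue numbering scheme with
    signature-motif extraction, a Nei-Gojobori dN/dS selection screen, a
    loss-of-function constraint comparison, and a gene-family simulator
    (duplication, loss, branch-specific selective pressure, chimeric
    recombinants) with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
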