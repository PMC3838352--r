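Package: strucnet
Title: Structure-Aware Phenotype Sub-Networks from Protein Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds phenotype-specific protein-protein interaction
    sub-networks from seed genes by guilt-by-association network
    propagation (NetScore, NetZcore, NetShort and their NetCombo
    consensus), transfers node scores to edges and extracts thresholded
    sub-networks with hub annotation. Overlays template-based models of
    binary protein complexes on the sub-network edges: two-chain
    interfaces are extracted from coordinate files, redundant structures
    are clustered by TM-score and RMSD, interface templates are matched
    rigidly onto target chains and the resulting models are filtered by a
    residue-contact energy. Statistical helpers test the source-organism
    composition of the templates (hypergeometric upper tail), perform
    gene-set term enrichment with Holm correction, and map point variants
    onto structures as core, surface or interface residues via
    solvent-accessibility sampling, with Fisher tests of location
    preference and a simple interface hot-spot rule. A synthetic-data
    module generates networks with planted phenotype modules, toy
    two-chain complexes, template libraries with controlled organism
    composition and variant tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    igraph,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    fgsea,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
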