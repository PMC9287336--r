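Package: gcevo
Title: Gene Content Evolution on Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene content evolution across a phylum-level
    species phylogeny. Provides Newick tree handling with relative
    evolutionary divergence (RED) and minimal-ancestral-deviation (MAD)
    rooting; a synthetic generator for gene families evolving under
    origination, duplication, intra-phylum transfer and loss with
    completeness censoring of metagenome-assembled genomes; a parsimony
    duplication-transfer-loss reconciliation engine plus readers for
    reconciliation summary tables; branch-by-mechanism event aggregation
    with punctuation scores and donor-recipient transfer matrices;
    ancestral genome content reconstruction with KO-level functional
    gain/loss deltas and independent trait-acquisition counting on gene
    trees; and genome taxonomy statistics based on average amino acid
    identity clustering, quality filtering and completeness-adjusted
    genome summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
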