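Package: svatools
Title: Diagnostic-Substitution Subfamily Classification and Network
    Phylogenetics for SVA Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the phylogenetic analysis of SVA retrotransposon
    expansion in hominine primates. Sorts element copies into hierarchical
    subfamilies from co-segregating diagnostic substitutions relative to a
    reference consensus, builds median-joining haplotype networks with
    maximum-parsimony post-processing and outgroup rooting, decides
    cross-species orthology of insertions from flanking sequence, analyses
    target-site duplications (pre-integration sites, untemplated 5' G,
    A-tract context), annotates SVA domain structure and detects
    non-canonical 5' exon-capture elements. A forward simulator of
    subfamily expansion on the hominine species tree provides ground truth
    for scoring every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
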