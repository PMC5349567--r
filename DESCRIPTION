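Package: phylopart
Title: Phylogenetic Entropy Partitioning of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions microbial community diversity over a rooted
    phylogeny using the phylogenetic generalization of Shannon entropy.
    Gamma and alpha diversity are reported as exponentials of phylogenetic
    entropy (equivalent numbers of equi-abundant independent lineages) and
    beta diversity as the mutual information between an observation's
    lineage and its group, decomposed into per-branch contributions and
    normalized by the grouping entropy into a turnover measure in [0,1].
    Includes equal-group weighting to neutralize unequal sequencing depth,
    a read-label permutation test of beta diversity, pairwise turnover
    distance matrices with principal coordinates analysis, OTU count
    filtering and candidate-phyla subsetting, iTOL annotation export, and
    a seedable synthetic community generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
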