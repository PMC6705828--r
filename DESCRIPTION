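Package: hpcphylo
Title: Hierarchical Phylogeny Construction for Isolate Panels with Mixed
    Similarity Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds phylogenies for large panels of sequenced isolates whose
    pairwise SNP rates span several orders of magnitude. Instead of one flat
    tree, the method partitions the isolates into a group of moderately
    similar isolates and subgroups of highly similar isolates (via an
    anchor-based estimate of the maximum pairwise distance and a distance
    ratio cutoff), constructs a smaller tree for each group from a
    column-subsampled alignment with an adaptive sample-size doubling loop,
    and recurses into the subgroups. Includes a benchmark dataset simulator
    (random true phylogenies, GTR sequence evolution, identity-column
    padding) and a Robinson-Foulds evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
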