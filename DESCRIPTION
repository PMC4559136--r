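Package: glycotaxa
Title: Glycome Statistics and Taxon Clustering for Carbohydrate Structure Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for statistical analysis of taxonomy-annotated glycan
    structure collections. Parses carbohydrate structures written in CSDB
    linear notation into residue/linkage graphs, enumerates monomeric and
    dimeric fragments under configurable residue filters, and computes
    per-taxon fragment abundance, uniqueness and database-coverage
    statistics. Taxa are compared through binary fragment-occurrence
    profiles (glycoprofiles): Hamming distances between profiles are
    normalized by per-taxon structure counts and rescaled to a maximal
    distance of 100, and the resulting dissimilarity matrices are clustered
    with UPGMA, complete linkage, Ward's method, neighbor joining, BIONJ
    and minimum-evolution trees, with Phylip/TSV/Newick/Nexus export and a
    topological tree-similarity score. A seeded synthetic-collection
    generator with planted taxon-specific fragment preferences supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    clue,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
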