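Package: crustnet
Title: Probabilistic Co-Occurrence Analysis and Networks for Biocrust Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact probabilistic pairwise co-occurrence analysis for binary
    samples-by-taxa incidence matrices, after the combinatorial model of
    Veech (2013). Each taxon pair is tested with the hypergeometric
    distribution of shared-sample counts, filtered on expected co-occurrence,
    and classified as positive, negative, or random. A taxon co-occurrence
    network is built from shared samples and characterised by degree,
    betweenness centrality, edge density, connected components,
    Newman-Girvan modularity, and a label-shuffling permutation test for
    modularity. A synthetic incidence-matrix generator with fixed column
    totals and optionally planted pairwise associations makes every stage
    testable, including a study-shaped fixture of 38 biocrust samples by
    23 taxa from a tropical granite-gneiss outcrop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
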