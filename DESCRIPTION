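Package: popgenmt
Title: Population Genetics of Mitochondrial Marker Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of aligned mitochondrial
    marker sequences sampled from hierarchically structured populations:
    haplotype collapsing and Coleman rarefaction, diversity indices (haplotype
    diversity, nucleotide diversity, mean pairwise differences), Tajima's D and
    Fu's Fs neutrality tests with coalescent simulation p-values, hierarchical
    analysis of molecular variance (AMOVA) with Phi-statistics and permutation
    tests, pairwise Phi-ST with island-model gene-flow conversion, Mantel tests
    of isolation by distance, mismatch distributions with sudden-expansion
    model fitting and parametric-bootstrap goodness of fit, statistical-
    parsimony haplotype networks, and seeded coalescent simulators for
    structured, expanding populations producing standard FASTA/TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
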