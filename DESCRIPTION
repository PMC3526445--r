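Package: kmcp
Title: Reconstructing Genome Mixtures from Partial Adjacencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact algorithms for the k-minimum completion problem:
    reconstructing rearranged genomes from an unattributed, incomplete
    multiset of adjacencies measured from a mixture of genomes derived from
    a common reference, as in bulk cancer sequencing. Implements the
    genome/adjacency data model with plain-text and signed-permutation
    input, breakpoint graphs and the double-cut-and-join (DCJ) distance
    with a breadth-first-search oracle, linear-time optimal completion of a
    single partial genome (unrestricted, circular unichromosomal and
    linear unichromosomal variants), an exact edge-coloring test for the
    existence of k-genome attributions, an exhaustive exact solver for
    tiny mixtures, constructive hardness gadgets reducing conjunction
    satisfaction to 2-genome mixtures, and a seeded simulator for
    synthetic partial multi-genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
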