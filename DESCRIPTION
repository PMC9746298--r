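Package: rgptyper
Title: In Silico Rgp Typing of Streptococcus thermophilus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying Streptococcus thermophilus strains by the
    genotype of their rhamnose-glucose polysaccharide (Rgp) biosynthesis locus.
    Implements an in-silico realisation of a two-step multiplex PCR typing
    scheme (variable side-chain and rhamnan-backbone genotypes, combined into
    binomial V x B names and Rgp groups), the legacy single-step
    classification PCR, extraction of the rgp locus between its flanking
    anchor genes, all-vs-all protein gene-family clustering of rgp loci with
    hierarchical presence/absence clustering, a curated knowledge base of Rgp
    chemical structures per genotype, and a deterministic synthetic-fixture
    generator that plants complete rgp loci of every genotype for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
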