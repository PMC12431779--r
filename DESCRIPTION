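Package: tspscan
Title: Quartet Bayes Factors for Trans-Species Polymorphism from Posterior Tree Samples
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects ancient trans-species polymorphism (TSP) at MHC-like
    loci from posterior samples of allele phylogenies. Induced unrooted
    quartet topologies are tallied over a tree sample and summarized as
    Bayes factors for allele-lineage sharing across species, maximized
    over allele quartets between two taxon groups, with a zero-count
    regularization for decisive samples. Companion tools detect candidate
    gene-conversion tracts between aligned alleles (a permutation-tested
    matching-runs statistic with a donor/acceptor direction heuristic) and
    emit per-exon exclusion lists; normalize per-site evolutionary-rate
    posteriors into log2 fold changes against a gappy-column baseline;
    and map per-codon rates onto peptide-bound protein structures via
    minimum atom-atom distances to the peptide chain. A synthetic-data
    generator emulates posterior tree sets under species-monophyly and
    TSP genealogies, alignments with planted rate classes and conversion
    tracts, rate posteriors, and toy peptide-groove structures, so the
    whole pipeline is testable without external samplers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape (>= 5.0),
    phangorn,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
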