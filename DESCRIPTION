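Package: hgcamplicon
Title: Degenerate Primer Evaluation and Functional-Gene Amplicon Analysis for hgcAB
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for auditing degenerate PCR primers and profiling
    functional-gene amplicon communities, built around the hgcAB mercury
    methylation marker. Provides IUPAC ambiguity-code algebra (degeneracy,
    variant enumeration, reverse complement, nearest-neighbor melting
    ranges), mismatch-constrained in-silico PCR with 3'-end mismatch
    protection, primer audit statistics (efficiency, specificity against
    ferredoxin paralogs, redundancy, per-variant occurrence, degeneracy
    reduction, equimolar subset selection), taxonomy-annotated reference
    packages (region-trimmed alignments, profile models, rooted trees),
    an amplicon processing pipeline (trimming, dereplication, chimera
    detection, greedy identity clustering, read mapping), phylogenetic
    placement with lowest-common-ancestor classification, community
    statistics (rank aggregation, rarefaction, sequencing error rate,
    weighted UniFrac, principal coordinates analysis), and synthetic-data
    generators for mock-community validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phyloseq
Config/testthat/edition: 3
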