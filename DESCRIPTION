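Package: crisprPairs
Title: Paired Guide RNA Design for CRISPR Deletion Screens
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design of ranked pairs of single-guide-RNA protospacers
    flanking genomic target regions, for CRISPR-Cas9 mediated genomic
    deletion. Candidate protospacers are discovered by NGG PAM scanning of
    strand-aware design regions, filtered by genome-wide off-target counts
    at exact Hamming distances 0-4 (with a coding-region NAG/NGG exclusion
    pass), scored for predicted cleavage efficiency with the Doench 2014
    Rule Set 1 logistic-regression model, assembled into upstream/downstream
    pairs, and prioritised under mask tiers, a per-protospacer diversity
    cap and DECKO dual-promoter cloning constraints. Includes a flat-file
    off-target database builder, batch drivers with summary statistics,
    and a synthetic-genome fixture generator with planted protospacers
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: CRISPR, SequenceMatching, FunctionalGenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
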