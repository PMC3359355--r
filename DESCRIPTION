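Package: somaticpair
Title: Somatic Variant Discovery in Tumor/Normal Whole-Genome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Re-usable implementation of a paired tumor/normal whole-genome
    somatic analysis: a per-strand, base-quality-weighted genotype caller
    built on a two-point Kolmogorov-Smirnov-style distance with strict and
    lenient (variant-consensus) tiers and a somatic classification rule; a
    two-step somatic small-indel detector with insert-size filtering and a
    normal-sample exclusion window; clone (fragment) coverage copy-number
    analysis with mode normalization and log2 tumor:normal segmentation;
    coding consequence annotation at codon level with transition/transversion
    and known-sites summary statistics; and a longitudinal mutation-
    acquisition timeline over multi-sample codon observations. A deterministic
    synthetic tumor/normal data generator (reference, truth sets, paired-end
    alignments with qualities, strands, inserts, duplicates and copy-number
    segments) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stringi,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
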