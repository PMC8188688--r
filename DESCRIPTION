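Package: natpairs
Title: Detection and Stress-Response Analysis of Natural Antisense Transcript Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide identification and classification of cis-natural
    antisense transcript (NAT) pairs from stranded transcript annotations.
    Classifies transcripts into mRNA, long intergenic noncoding RNA (lincRNA)
    and long noncoding natural antisense transcript (lncNAT) categories,
    detects opposite-strand transcript pairs above a minimum overlap and types
    them as enclosed, divergent (head-to-head) or convergent (tail-to-tail),
    calls stress-responsive pairs from replicated FPKM expression tables
    (fold-change and Benjamini-Hochberg FDR thresholds, with concordant and
    discordant classification), partitions findings across plant accessions as
    three-set Venn regions, links sense partners to stress-related Gene
    Ontology terms by hypergeometric enrichment, and computes the leaf
    water-loss and 2^-delta-delta-Ct bench formulas. Includes a seeded
    synthetic-annotation and expression simulator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
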