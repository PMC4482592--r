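Package: PoolSift
Title: Strain-Differential Mutation Calling and Expression Consensus for
    Pooled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative wild-versus-albino transcriptome
    inference from pooled RNA-seq libraries. Calls strain-differential
    candidate mutations from PoPoolation2 synchronized allele counts
    (alleles well supported in every wild-type pool but absent from every
    albino pool), assesses per-pool homozygosity and albino-homozygous
    deletions, and annotates called sites against predicted open reading
    frames on de novo contigs (5'/3' UTR or CDS placement, synonymous,
    nonsynonymous, stop and indel consequences). Merges two
    differential-expression result tables into candidate and definite
    tiers under Benjamini-Hochberg false-discovery control, derives
    reciprocal-best-hit orthologs from BLAST tabular output under
    alignment-length, identity and E-value gates, and cross-references a
    pigmentation gene panel against expression and mutation results.
    Ships seeded generators for synthetic transcriptomes, synchronized
    files and negative-binomial count matrices with planted ground truth
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
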