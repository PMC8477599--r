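Package: poolfactor
Title: Factorial Analysis of Pooled Allele-Frequency Data from Larval
    Selection Experiments
Version: 0.1.0
Authors@R: person("Pool", "Factor", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pooled-DNA (pool-seq) allele-frequency analysis of
    replicated factorial selection experiments on bivalve larvae: read-level
    quality control and SAM-to-nucleotide-count conversion for uniform
    36-bp restriction tags, a locus-retention filter cascade (depth,
    biallelic, one SNP per tag, replicate presence, minor-allele
    frequency), per-locus binomial generalized linear models with type III
    likelihood-ratio tests and Benjamini-Hochberg classification of stage,
    treatment, additive and interactive effects, pool-adapted nucleotide
    diversity and pairwise FST with bootstrap confidence intervals,
    linkage-map bridging of SNPs to linkage groups via shared genomic
    scaffolds, and gene-score-resampling functional enrichment over Gene
    Ontology terms.  A synthetic-data generator emulates the replicated
    two-stage, two-treatment pooled design with a drift layer and ground
    truth so that power and false-discovery behaviour can be evaluated
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
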