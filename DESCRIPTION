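Package: longrna
Title: Read-Length Effects in RNA-Seq: Merging, Concordance, Isoform
    Assignment and Allele-Specific Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how sequencing read length affects bulk
    RNA-seq analyses. Implements overlap merging of paired-end reads whose
    cDNA fragment is shorter than the read length, RNA/DNA genotype
    concordance scoring with a binomial discordance test, per-base
    feature-set assignment of aligned fragments to genes and mRNA isoforms
    with splice-junction consistency, unique-base transcript quantification,
    detection of allele-specific expression and allele-specific alternative
    splicing with reference-bias (mapping retention) filtering, Poisson
    extrapolation of haplotype-assignable read fractions to longer read
    lengths, and a sequencing-cost model with read-, base- and cost-matched
    library subsampling. Ships a diploid transcriptome simulator (phased
    heterozygous sites, multi-isoform gene models, pseudogene-like duplicated
    loci, adapter read-through for short fragments) and an exhaustive toy
    aligner so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
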