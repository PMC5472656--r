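Package: slatyper
Title: Sequence-Based Genotyping of Expressed Swine MHC (SLA) Class I Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping of the classical swine leukocyte antigen (SLA) class I
    loci (SLA-1, SLA-2, SLA-3) from barcoded paired-end cDNA amplicon
    sequencing. Implements in-silico PCR with degenerate primers and amplicon
    resolvability analysis against an allele reference library; a full read
    pipeline (barcode demultiplexing, quality trimming, ungapped paired-end
    merging, 100 percent-identity dereplication, cluster size filtering,
    two-parent chimera detection and splice-variant/off-size artifact
    removal); per-animal allele calling with read-fraction transcription
    proxies and novel-allele discovery; population-level haplotype inference
    from homozygous seed animals; and phylogenetic locus placement of novel
    alleles by neighbor-joining on Jukes-Cantor distances with bootstrap
    support. A seeded simulator generates fixture allele libraries and
    barcoded paired-end reads with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
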