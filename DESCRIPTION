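Package: panmicrodiv
Title: Pangenome Construction and Core-Genome Micro-Diversity Analysis for
    Bacterial Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study strain-level micro-diversity in bacterial species
    such as Lactobacillus crispatus. Clusters genes from a set of strain
    genomes into orthologous families, partitions the pangenome into core,
    accessory and strain-unique genes, extracts occurrence-filtered single
    nucleotide polymorphisms from concatenated core genes, normalises them to
    SNPs per Mbp, flags highly variable genes by an interquartile-range
    outlier rule, reconstructs neighbour-joining phylogenomic trees with
    bootstrap support, selects strain-specific marker genes and deconvolves
    strain proportions in shotgun metagenomes of defined co-cultures by
    perfect-match read counting and RPKM. A coalescent-based pangenome and
    read-mixture simulator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
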