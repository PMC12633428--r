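Package: mosaikit
Title: Diagnosing Hybrid Diploid Genomes from Variants, Depth and
    Modification Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational procedures for diagnosing the genome of an
    allodiploid hybrid: windowed heterozygosity and strain divergence,
    loss-of-heterozygosity (LOH) tract calling and classification,
    parent-of-origin mosaic painting of hybrid haplotypes, read-depth
    aneuploidy and partial copy-number calling, TSS-anchored 5mC/6mA
    methylation metaprofiles with periodicity estimation, and
    transcript-curation rules (isoform filtering, primary-isoform
    selection, Kozak-model ORF extension, antisense lncRNA
    classification). Includes a synthetic allodiploid genome generator
    with a truth log so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
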