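Package: allomap
Title: Subgenome Assignment, SNP Marker Design and Comparative
    Gene-Block Mapping for Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the transcriptome of an allotetraploid
    crop with two diploid progenitor genomes. Assembled contigs are
    classified to their constituent subgenome by a two-step protein /
    nucleotide identity search against dual diploid references; variants
    between two accessions are called and separated into allelic SNPs,
    homoeologue-specific variants (HSVs) and paralogue-specific variants
    (PSVs); KASP-suitable co-dominant markers are designed with depth,
    conserved-flank and exon-junction filters; a doubled-haploid linkage
    map is built with LOD-threshold grouping and Kosambi map distances;
    and linkage groups are painted with ancestral crucifer gene blocks
    (A-X) to infer homoeology, block fragmentation and block-association
    motifs between the two subgenomes. A synthetic-data module generates
    allopolyploid inputs with known truth so every stage is testable
    without external downloads.
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
    data.table,
    graphics,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
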