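Package: polycap
Title: Targeted Sequence Capture Analysis of Homoeologous Gene Copies in
    Allopolyploid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted sequence-capture experiments in allopolyploid
    species such as Brassica napus, where every gene may be present as multiple
    homoeologous and paralogous copies. Provides capture quality-control metrics
    (enrichment factor, target sensitivity, on-target specificity), read-depth
    normalization and ratio-threshold calling of copy-number and
    presence-absence variation across a genotype panel, classification of
    variants into homozygous SNPs and heterozygous hemi-SNPs arising from
    collapsed homoeologous loci, synonymous/non-synonymous annotation against
    CDS models, bookkeeping of detected versus progenitor-expected gene copies,
    tiling of 120-mer capture baits, and neighbor-joining clustering of promoter
    sequences with bootstrap support. A synthetic-data generator simulates a
    complete allopolyploid capture experiment (depth tracks, variants, truth
    tables) so every step can be exercised and validated without access to
    sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
biocViews: Sequencing, TargetedResequencing, CopyNumberVariation, SNP,
    Coverage, Phylogenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
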