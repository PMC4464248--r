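Package: tpsminer
Title: Genome Mining and Comparative Analysis of Terpene Synthase Gene
    Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers terpene synthase (TPS)-like loci in genome
    assemblies by translated seed-and-extend homology search, builds
    exon-chain gene models guided by reference templates, tallies
    frameshifts and premature stop codons, and classifies every locus
    into a five-category functional/pseudogene rubric. Additional
    components score diagnostic active-site motifs (RR(x)8W, RLLR,
    DDxxD, NSE/DTE), detect tandem gene clusters and their per-gene
    density, pair orthologs between two species by reciprocal best
    hits, place genes into TPS subfamilies, build neighbor-joining
    trees with bootstrap support, and bi-cluster tissue expression
    (FPKM) matrices. A synthetic-genome forge plants multi-exon gene
    families with a machine-readable truth ledger so every stage of
    the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: Genetics, GenomeAnnotation, Phylogenetics, GeneExpression,
    Clustering, SequenceMatching
Config/testthat/edition: 3
RoxygenNote: 7.3.3
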