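Package: tetrasnp
Title: SNP Discovery, Homoeolog Filtering and Graphical Genotyping for
    Allotetraploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-backed toolkit for single nucleotide polymorphism
    (SNP) genotyping in allotetraploids with two highly similar subgenomes,
    where homoeologous sequence differences confound allelic variant
    discovery. Provides a ground-truthed simulator of paired subgenomes,
    homozygous-divergent parental lines, near-isogenic recombinant inbred
    line (RIL) pairs and target-enrichment / RNA-seq / genotyping-by-
    sequencing read sets; capture probe panel design with uniqueness
    evaluation and spacing selection; identity-stratified capture target
    regions and coverage metrics; a deterministic seed-and-extend read
    aligner supporting separate-subgenome and concatenated reference
    strategies; five SNP calling and filtering pipelines that separate
    allelic from homoeologous variants by read depth, homoeolog-anchored
    read partitioning or read-level haplotypes; concordance scoring against
    array genotypes; and graphical-genotype mapping of polymorphic regions
    between sister RILs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
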