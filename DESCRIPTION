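Package: ssrkit
Title: Genome-Wide Microsatellite Marker Discovery and Diversity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for developing simple sequence repeat (SSR) markers
    from a genome assembly and applying them to genetic-diversity analysis.
    Detects perfect microsatellites under per-class minimum-repeat
    thresholds, canonicalizes motifs under rotation and reverse complement,
    flags compound loci, classifies loci by genomic context against GFF3
    gene models, designs locus-specific primer pairs under a
    nearest-neighbor melting-temperature model with cross-pair uniqueness
    filtering, anchors scaffolds to linkage groups by mean SNP genetic
    position, and names markers by motif class, linkage group and serial.
    A codominant-marker layer computes per-locus diversity statistics
    (Na, Ng, major allele frequency, Ho, He, PIC), Dice band similarity,
    UPGMA dendrograms, and model-based population clustering by an EM
    allele-frequency mixture with Evanno delta-K model selection.
    Synthetic genomes with planted repeats and simulated genotype panels
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Microsatellite, Clustering
RoxygenNote: 7.3.3
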