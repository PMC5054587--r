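Package: aposeq
Title: Deletion Mapping, Small RNA Profiling and Expression Analysis for
    Polyploid Apomict Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for transcriptome-based genetics in polyploid aposporous
    apomicts: deletion-marker discovery from SNP genotype patterns across a
    parent and deletion mutants, small RNA tag filtering, genome placement and
    genic annotation with 500 bp flanks, MIRNA hairpin locus prediction from
    perfectly aligned tag pairs, TMM-normalised negative-binomial exact-test
    differential calling, GO enrichment with one-to-many orthology count
    weighting, directional overlap and complementary sRNA/mRNA target
    integration, delta-delta-Ct qPCR calling, and a k-mer Hamming redundancy
    profiler for draft assemblies. Includes a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
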