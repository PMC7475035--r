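Package: tandemCNV
Title: Copy-Number Genotyping and Molecular Population Genetics of Tandem
    Multigene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing recently formed tandem multigene
    families from genome assemblies, short reads and qPCR assays. Implements
    copy-number genotyping from read depth against synthetic single-repeat
    references (averaged normalized read depth with call-size reliability
    filtering), dual-amplicon efficiency-corrected qPCR copy-number calls,
    protein-variant (paratype) classification of tandem copies from
    diagnostic amino-acid blocks, V_ST population differentiation with a
    Monte Carlo null, zero-mismatch gene-conversion tract detection with
    permutation-based familywise correction, motif-anchored counting of
    transcript evidence in RNA-seq reads, and expression/sperm-competition
    statistics. A synthetic-data generator emulates tandem-array regions
    with known truth, Illumina-like reads, qPCR Ct tables, population
    copy-number samples and binomial progeny counts, so every analysis is
    exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
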