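Package: introkit
Title: Detecting and Characterizing Interspecific Introgression from SNP
    Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring gene flow between species from biallelic
    SNP genotypes and phylogenetic trees: frequency-weighted ABBA-BABA
    D and f_d site-pattern statistics with block-jackknife standard
    errors, f4-ratio admixture-proportion estimation, windowed f_d
    genome scans with empirical-percentile outlier calling, localization
    of introgressed haplotypes by diagnostic fixed-difference sites and
    genotype painting, gene-tree/species-tree displaced-taxon detection,
    crown-age scaling of node divergence times, coding-sequence
    translation and diagnostic-residue search, and introgression-order
    reasoning from haplotype-tract decay under recombination. Includes a
    seedable multi-species genotype simulator with planted introgression
    tracts so every stage can be validated against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, Phylogenetics, SNP, Genetics, Software
RoxygenNote: 7.3.3
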