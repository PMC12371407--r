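Package: baculopop
Title: Population Genomics of Baculovirus Epidemics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the population genomics of baculovirus
    epidemics from multi-isolate consensus genomes and multi-sample variant
    calls. Implements biallelic minor-allele-frequency filtering and
    segregating-site selection, between-host and within-host nucleotide
    diversity (pi) and per-gene Watterson's theta, coding-consequence
    classification of SNVs, indels and microsatellite variants, homologous
    repeat (hr) palindrome scanning, discriminant analysis of principal
    components (DAPC) with BIC-based cluster-number selection, classification
    of within-host allele-frequency patterns into single, two-strain and
    multi-strain infections, and wave-level epidemic trend statistics with
    missing-stratum imputation and stratified permutation tests. A seeded
    synthetic epidemic generator emulates multi-year, multi-season outbreaks
    with founder bottlenecks so that every stage of the pipeline can be
    validated against known truth.
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
    MASS,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: PopulationGenetics, SNP, Genetics, Epidemiology, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
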