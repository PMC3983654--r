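Package: zebramel
Title: Somatic Mutation Analysis of Engineered Zebrafish Melanoma Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis toolkit for low-burden, UV-independent
    melanoma exome studies in transgenic zebrafish. Provides a seeded
    synthetic cohort generator emulating a 53-sample engineered-melanoma
    study; a simulation harness for benchmarking somatic substitution
    callers under germline SNP density and normal-contamination gradients;
    somatic SNV and indel filtering with toy gene-model consequence
    annotation; pyrimidine-folded mutation spectrum and strand-bias
    analysis with kataegis-style cluster detection; a 12-rate
    mutation-selection (dN/dS) maximum-likelihood model with likelihood
    ratio tests; ploidy-aware copy-number amplification and homozygous
    deletion calling with a length-preserving permutation recurrence test;
    a combined binomial per-gene significance statistic across mutation
    modalities with threshold-swept pathway enrichment; and mutation-burden
    covariate models (age, engineered driver count).
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
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
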