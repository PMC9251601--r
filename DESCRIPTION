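Package: TriOmicNet
Title: Population-Scale Multi-Omics Integration into Tripartite
    Metabolite-Gene-eQTL Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates population-scale genotypes, a pan-transcriptome
    expression matrix and metabolite abundances into a tripartite
    metabolite-gene-eQTL regulatory network. Provides variant filtering,
    LD pruning, genotype PCA, VanRaden kinship and per-SNP Weir-Cockerham
    Fst; expression-layer classifications (core/near-core/accession-specific
    presence classes, HEG/MEG/LEG abundance classes, expression
    presence/absence variation, differential expression) and differentially
    accumulated metabolite signatures; GLM and single-variance-component
    mixed-model (P3D) association scans with permutation significance
    thresholds, quantitative trait transcript (QTT) regression and
    cis/trans eQTL classification; candidate-gene colocalization and
    network assembly with pleiotropy/richness annotations. A seeded
    synthetic multi-omics generator with planted ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
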