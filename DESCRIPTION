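Package: famevol
Title: Gene Family Expansion, Duplication and Molecular Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reusable pipeline for genome-wide analyses of large receptor-like
    kinase gene families, modelled on the leucine-rich repeat receptor-like
    kinase (LRR-RLK) family of soybean. Covers domain-criterion family
    identification, neighbor-joining phylogeny of kinase domains with
    bootstrap support and reference-guided group assignment, tandem and
    segmental duplication classification, Nei-Gojobori Ka/Ks estimation with
    synonymous-clock dating of duplication events, expression-profile
    clustering and duplicate-divergence calls, qPCR relative expression, and
    a wild-versus-cultivated selection scan from per-SNP gene diversity and
    Fst. A synthetic-data module generates every input with planted ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
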