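Package: ribovar
Title: Inter-Individual Variation in RNA Expression, Ribosome Occupancy and
    Translation Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for multi-individual,
    multi-replicate ribosome profiling and RNA-seq studies. Normalizes count
    libraries (TMM and voom precision weights), estimates per-individual
    translation efficiency by weighted linear models, identifies genes with
    significant inter-individual variance via a simulation-based exact
    likelihood ratio test for a single variance component, scans haplotype
    5' UTR sequences for upstream open reading frame (uORF) changes and tests
    their association with ribosome occupancy, scores Kozak-region variants
    with a position weight matrix, integrates RNA, ribosome occupancy,
    translation efficiency and protein levels with a self-organizing map and
    affinity propagation clustering, maps cis-QTLs, and performs
    permutation-corrected gene set enrichment. Ships a synthetic-study
    generator with planted ground truth so every stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    edgeR,
    limma,
    lme4,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
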