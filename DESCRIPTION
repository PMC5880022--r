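Package: methvar
Title: Inter-Individual DNA Methylation Variability and Evolutionary
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for inter-individual DNA methylation
    variability (MV, the per-probe standard deviation of beta-values
    across individuals) and its relation to genomic and evolutionary
    features: probe filtering and MV computation for array-style
    methylomes, sequence-based CpG cluster discovery and
    high/intermediate/low density classification, intersection with
    base-resolution conservation (GERP-RS) tracks and quartile trend
    tests, recent-positive-selection SNP filtering with a Monte Carlo
    bootstrap comparison of MV in selected windows, and promoter-level
    gene ranking with a self-contained preranked gene-set enrichment
    analysis. Includes a synthetic-data generator that plants all the
    expected couplings so the full pipeline is testable end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    limma
Config/testthat/edition: 3
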