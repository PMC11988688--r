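Package: ervantigen
Title: Discovery of HIF2-Responsive, HLA-Presented Endogenous Retrovirus Antigens
Version: 0.1.0
Authors@R:
    person("ERV", "Antigen Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering hypoxia-inducible-factor
    (HIF2)-responsive, translated, HLA-presented endogenous retrovirus (ERV)
    antigens in clear cell renal cell carcinoma and related settings. Implements
    ERV expression quantification from transcriptome-unmapped alignment evidence
    (paired-end/single-end retention rules, fragment deduplication, 2x paired +
    1x single counting, library-size and length normalization), HIF2
    responsiveness calling with Venn tiering and candidate-set union, ChIP
    peak-to-ERV proximity annotation at configurable windows, ERV-aware six-frame
    proteogenomic search-database construction with I/L-collapsed peptide-source
    mapping and unique 9-mer accounting, and the multi-metric immunopeptidomics
    PSM filtering machine (target-decoy FDR, fixed score thresholds,
    spectral-angle/retention-time/HLA-rank strike classification, and the
    normal-tissue/redundancy/cysteine/strike peptide filter chain). A synthetic
    data module provides ground-truthed catalogs, alignments, PSM tables and
    expression matrices so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
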