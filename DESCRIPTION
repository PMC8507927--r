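Package: dropscreen
Title: Pooled shRNA Dropout Screen Simulation, Quantification and
    Essentiality Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for pooled short-hairpin RNA (shRNA)
    negative-selection screens: models the gene/shRNA/barcode library
    catalogue, simulates selection-driven barcode depletion with planted
    (optionally condition-specific) essential genes down to FASTQ reads,
    quantifies barcodes into a count matrix with mismatch-tolerant
    matching and per-sample QC, and ranks genes for essentiality by the
    second-largest depletion fold change among each gene's shRNAs.
    Also implements the Chou-Talalay median-effect model (IC50,
    effect-equivalent doses, combination index and its qualitative
    classification) for drug-synergy analysis, and the post-processing
    rules for differential-expression tables (strict retention filter
    and the signed -log10 p pre-ranking metric used for gene set
    enrichment analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
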