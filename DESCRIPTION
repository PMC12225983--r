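Package: organelleMA
Title: Organelle Germline Mutation Rates from Mutation-Accumulation Line
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Heteroplasmic variant detection and germline mutation-rate
    estimation for plant mitochondrial and plastid genomes sequenced in
    mutation-accumulation (MA) line experiments. Implements a threshold-based
    filtering cascade over per-site allele-count tables (frequency, depth and
    wild-type background filters, large-repeat and structural-artefact
    exclusion, correction of mitochondrial allele frequencies for
    numt-derived reads), frequency-weighted mutation-rate estimators with
    Poisson zero-observation upper bounds, mutation-spectrum analysis
    normalized by base-pair composition, homopolymer and dinucleotide-repeat
    indel context analysis, a spectrum-preserving permutation test for
    synonymous-site enrichment, and a Poisson overdispersion test across
    lines. A synthetic-data module simulates MA pedigrees with planted
    heteroplasmic mutations, transmission-bottleneck drift, depth and
    sequencing-error models, and numt contamination, providing ground truth
    for every downstream stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
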