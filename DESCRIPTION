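Package: strandrepair
Title: Strand-Resolved Analysis of DNA Damage and Excision Repair Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for strand-resolved analysis of cisplatin-induced DNA damage
    (Damage-seq) and nucleotide excision repair (XR-seq). Implements positional
    Pt-d(GpG) lesion filtering of aligned reads against a reference genome,
    assignment of lesions to the transcribed (TS) and non-transcribed (NTS)
    strands of annotated genes, GG-dinucleotide and library-size normalization,
    the TS/(TS+NTS) ratio and the transcription-coupled repair (TCR) fraction
    estimator 1 - Damage_TS/Damage_NTS, expression-quantile stratification,
    pseudo-reference relative damage, mitochondrial background contrasts, and
    gene-level epigenomic track association. Ships a kinetic forward simulator
    (uniform per-GG-site Poisson damage, exponential strand-specific repair)
    that emits Damage-seq, XR-seq and RNA-seq data with known truth, so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
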