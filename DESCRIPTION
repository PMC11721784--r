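Package: denovopop
Title: Population-Scale Presence, Evolution and Selection Analyses of De Novo Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recently born (de novo) genes in resequenced
    plant populations. Calls gene presence or absence per accession by applying
    loss-of-function variants (start loss, premature stop, stop loss,
    frameshift) to the reference coding sequence; summarizes presence
    frequencies per population into spectrum bins and nearly-fixed/low-frequency
    classes; contrasts gene features between frequency classes with
    Wilcoxon rank-sum tests; reconstructs ancestral open reading frames by
    outgroup-rooted Fitch parsimony and annotates per-branch synonymous,
    nonsynonymous, stop-gain/loss and indel events in a fixed reference reading
    frame; scans flanking sequence for target-site-duplication motifs; filters
    tabular homology hits; tests environmental association of presence status
    with an equal-variance t test and a subsampling permutation null; scans
    haplotype matrices for selective sweeps with the linkage-disequilibrium
    omega statistic; and generates synthetic data sets with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
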