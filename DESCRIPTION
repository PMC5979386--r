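Package: degradomiR
Title: Small RNA miRNA Discovery and Degradome-Based Target Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested re-usable pipeline for plant small-RNA analysis in
    genome-less (unigene-based) species: cleaning and collapsing of sRNA-seq
    reads, identification of known miRNAs against a miRBase-style mature
    catalog, novel miRNA prediction by hairpin folding of unigene flanking
    sequence with a built-in nearest-neighbor minimum-free-energy folder,
    miRNA* and palindromic-precursor detection, RPM/FPKM quantification and
    fold-change differential expression, degradome (PARE) cleavage-site
    calling with Allen complementarity scoring, five-category site
    classification and permutation p-values, and hypergeometric GO term
    enrichment. Includes a synthetic-data generator that plants miRNA
    precursors, tissue-specific expression and cleavage sites with a
    machine-readable truth table for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
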