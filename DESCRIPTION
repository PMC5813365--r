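Package: srnacascade
Title: Tiered Small RNA-Seq Read Classification, Novel miRNA Filtering and
    Biomarker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable small RNA-seq analysis engine: adapter/barcode/length
    preprocessing; a four-tier alignment cascade that partitions every read
    among target-organism transcripts, the target genome (with novel miRNA
    hairpin prediction), a k-mer based pathogen screen, and cross-species
    miRNA precursors; stringent three-criterion quality filtering of predicted
    hairpins (score, decoy similarity, dinucleotide-shuffle structure p-value);
    a ranked top-N pathogen species report with precision/recall/F evaluation;
    and a balanced-sampling, feature-pruning random-forest biomarker module
    with out-of-bag and cross-validated performance. Includes a deterministic
    synthetic-data generator with known read provenance for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
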