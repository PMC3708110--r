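Package: srnatlas
Title: Small Non-Coding RNA Deep-Sequencing Analysis for Endothelial Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for profiling small non-coding RNAs from deep
    sequencing of endothelial cells: adapter clipping, read collapsing and
    abundance filtering, mismatch-bounded mapping of tags to microRNA
    references and a genome, ncRNA class annotation, isomiR and star-strand
    analysis, novel microRNA hairpin discovery with a built-in RNA secondary
    structure folder, snoRNA- and tRNA-derived fragment profiling, and
    reads-per-million expression tables. Includes a synthetic small RNA
    library generator with a ground-truth manifest so every stage of the
    pipeline can be verified without access to the original sequencing run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
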