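Package: endscan
Title: Differential Transcript-End Calling from Strand-Specific RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls condition-specific 5' and 3' transcript ends by comparing
    strand-specific per-base coverage topology between a reference and a test
    condition. Includes an exact-match read mapper with iterative 3'-end
    trimming, simulated-read gene mappability, poly(A) end-tag recovery and
    clustering, upstream-ORF and IUPAC-degenerate RNA-binding-protein motif
    scanning in differential ends with sampling-based enrichment z-scores, and
    a synthetic-data generator that plants differential ends, uORFs and
    poly(A)-tailed reads with machine-readable ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
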