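Package: fragbam
Title: Reconstruct Paired-End Alignments from De-Identified cfDNA Fragment Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts non-sensitive cell-free DNA (cfDNA) fragment coordinate
    files (BED, BEDPE, or FinaleDB-style TSV) into valid, coordinate-sorted
    paired-end alignment (SAM/BAM) files by filling in sequence from an
    indexed reference genome, and performs the inverse de-identification
    (BAM to fragment coordinates). Also implements downstream fragmentomics
    analyses on either representation: fragment length distributions, the
    short-fragment (< 150 bp) ratio, per-sample log2 length enrichment
    against a cohort, and nucleosome coverage-dip z-scores at interval sets
    such as cell-type-specific DNase hypersensitivity sites. A synthetic
    cohort generator produces reference genomes and FinaleDB-style fragment
    files with controllable mono-/di-nucleosome length mixtures, mapping
    qualities, strands, and planted coverage dips.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
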