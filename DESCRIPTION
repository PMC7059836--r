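Package: consensusvc
Title: Multi-Caller Consensus Variant Integration and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale reimplementation of the call-set integration
    strategy behind the 1000 Genomes GRCh38 biallelic SNV and INDEL
    release: normalization of variant representation (left-alignment,
    multiallelic split/merge, decomposition into allelic primitives),
    annotation-based hard filtering with the released cutoff tables and
    an empirical cutoff-derivation procedure, union-based consensus with
    per-caller provenance, and an evaluation suite covering gold-standard
    site concordance within high-confidence regions, haplotype
    switch-error rate, false-negative attribution by filter label, and
    novel-contig stratification. A synthetic-data module simulates a
    diploid truth panel and discordant multi-caller call sets with known
    parameters so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
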