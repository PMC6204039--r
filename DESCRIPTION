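Package: wgdtrace
Title: Reconstructing Whole-Genome-Duplication Histories from Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct paleopolyploidy (whole-genome duplication,
    WGD) histories anchored on a focal gene family. Implements codon-level
    synonymous substitution (Ks) estimation with the Nei-Gojobori (1986)
    counting method and Jukes-Cantor correction, protein-guided codon
    alignment, saturation and GC3 filtering, dynamic-programming chaining of
    homolog anchor pairs into collinear synteny blocks, syntelog extraction
    and cross-genome locus networks, support-based duplication detection on
    gene trees (the BS-1/BS-2/BS-3 criterion) with taxon-exclusion series and
    subfamily nomenclature, Ks-distribution dating (confidence intervals,
    kernel-density peaks, matching against a packaged literature table of WGD
    Ks ranges, rate/time calibration), and a fractionation-aware gene-family
    simulator that emits ground-truthed datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
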