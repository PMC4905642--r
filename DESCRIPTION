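Package: tescape
Title: Transposable-Element Genome Architecture and Expression-Impact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the transposable-element (TE) landscape of
    compact fungal genomes: building and filtering TE consensus libraries,
    annotating and defragmenting genomic copies with a built-in seed-and-extend
    local similarity search, dating LTR-retrotransposon insertions from LTR
    divergence under the Kimura two-parameter model, detecting solo-LTRs,
    finding TE-enriched clusters by hypergeometric sliding-window scans with
    FDR control, genotyping polymorphic insertions between haplotypes from
    whole-genome-alignment block maps, and testing whether TE neighbourhoods
    repress the expression of nearby genes. A synthetic-genome simulator with
    full ground truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
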