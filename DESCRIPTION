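Package: introscan
Title: Structural-Variant Patterns, TE Chronology and Introgression Timelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing population introgression with structural
    variants (SVs). Implements assembly-versus-assembly SV discovery by
    unique-k-mer anchoring, collinear chaining and gap arithmetic; merging of
    per-genome calls into a nonoverlapping catalog; classification of catalog
    SVs into population-specific presence/absence patterns with chromosomal
    enrichment tests; read-backed presence/absence genotyping against local
    references using breakpoint-flanking coverage criteria; transposable
    element (TE) family attribution, greedy consensus clustering and
    subfamily splitting by cosegregating mutations; Kimura two-parameter
    divergence dating with CpG correction; and origination-interval and
    minimum-origins inference on dated population trees, including a
    deterministic multi-phase admixture/selection haplogroup simulator. A
    synthetic-data module generates reference and derived genomes with
    planted pattern-structured SVs, diverged TE copies and error-bearing
    short reads, with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
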