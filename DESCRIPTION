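Package: mtmlsa
Title: Universal Degenerate Primer Design and Mitochondrial Multi-Locus
    Haplotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising insect populations from mitochondrial
    multi-locus sequence analysis (mtMLSA). Designs taxonomically universal
    degenerate PCR primers from multiple sequence alignments under explicit
    length and degeneracy budgets, screens candidates for hairpins and
    primer dimers, predicts amplicons by in-silico PCR on circular
    mitogenome templates with a single-band success rule, and assigns
    per-locus and concatenated haplotypes to demonstrate the resolution
    gain of locus concatenation. Includes a seeded simulator of circular
    mitogenome populations with planted primer-landing blocks, haplotype
    classes and tRNA-order rearrangements, and bundles the published
    Diptera and Lepidoptera universal primer tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
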