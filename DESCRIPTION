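Package: primercover
Title: In Silico Coverage Evaluation of Degenerate 16S rRNA Gene Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates degenerate 16S rRNA gene primers and primer pairs
    against species-annotated, reference-aligned amplicon sequence variant
    (ASV) databases. Implements IUPAC-aware zero-mismatch matching,
    variant-level (VC) and species-level (SC) coverage, position statistics
    with mode tie-breaking, hypervariable-region assignment in an
    Escherichia coli reference frame, primer-pair enumeration with
    admission rules, amplicon length categories, and bacteria/archaea
    specificity classification. Includes a deterministic synthetic fixture
    generator with an independent brute-force oracle, a reference-frame
    normalizer based on pairwise global alignment, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
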