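Package: varcat
Title: Constraint-Based Representation and Matching of Categorical Genomic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents categorical variants - sets of genomic alterations
    defined intensionally by shared, computable properties - as conjunctions
    of constraints (defining allele, defining location, copy count, copy
    change, feature context, functional consequence, adjacency). Provides
    fully-justified allele normalization with stable digest identifiers,
    membership matching of assayed variants (ingested from VCF) against
    categorical definitions with per-constraint explanation traces, sound
    entailment (subsumption) between categories, named structural profiles
    for common category shapes, and a synthetic finite-universe generator
    with a brute-force oracle for verifying matching and entailment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    digest,
    withr,
    vcfR,
    Biostrings,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
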