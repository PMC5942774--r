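Package: cibr
Title: Codon Information Bias Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the rescaled Kullback-Leibler codon information bias
    (CIB) for every gene of a coding-sequence collection and provides the
    downstream comparative machinery used in codon-usage studies of
    bacterial consortia: a two-stage distribution comparison (ties-adjusted
    two-sample Anderson-Darling test followed by permutation tests for
    stochastic dominance), COG-category and gene-length summaries,
    correlation-distance average-linkage clustering of strains, and a
    synthetic coding-sequence simulator with a closed-form population CIB
    for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
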