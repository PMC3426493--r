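Package: dupasym
Title: Asymmetric Evolution of Gene Duplicates from Codon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise asymmetric sequence evolution of
    gene duplicates (e.g. whole-genome-duplication paralogs) against an
    outgroup ortholog. Provides Nei-Gojobori style per-branch counting of
    synonymous and non-synonymous substitutions on a duplicate-pair-plus-
    outgroup trio, Fisher exact tests of rate asymmetry at the whole-protein,
    combined-domain, domain-specific and linker levels with
    Benjamini-Hochberg false discovery control, a Goldman-Yang codon model
    with likelihood-ratio testing of branch-wise dN/dS, downstream pattern
    statistics (clustering of non-synonymous changes within domains, domain
    assortment, faster-copy concordance, interleaving runs test), BLOSUM62
    substitution-severity scoring, spatio-temporal expression divergence
    scoring, and a codon-evolution simulator for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
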