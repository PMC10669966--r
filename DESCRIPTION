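Package: lpsdeg
Title: Subtype-Specific Highly Expressed Gene Discovery for Liposarcoma RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for finding genes highly expressed in one
    liposarcoma subtype relative to the others from bulk RNA-seq count data.
    Implements CPM/log-CPM quality-control filters, construction of a
    tissue-specificity exclusion list from an expression compendium
    (per-tissue top-k membership rules), one-vs-rest negative-binomial
    conditional exact tests with common and tagwise dispersion estimation,
    hypergeometric gene-set over-representation against GMT libraries, and
    the downstream clinical statistics used to validate candidate targets:
    immunohistochemistry H-scores with quartile and low/high binning,
    delta-delta-Ct relative quantification, viability-plate normalization,
    and exact Fisher-Freeman-Halton r x c contingency tests. Ships seeded
    synthetic-data generators with known ground truth so the whole pipeline
    is testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
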