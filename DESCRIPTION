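Package: cnsig
Title: Copy Number Signature Analysis from Segmented Absolute Copy Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extracting and quantifying somatic copy number
    alteration signatures from segmented absolute copy number profiles.
    Profiles are summarised by eight genome-wide copy number features
    (breakpoint counts per 10 Mb and per chromosome arm, segment copy
    number, copy number change points, oscillating copy number chain
    lengths, segment sizes, NC50 and per-chromosome alteration burden),
    classified into a fixed 80-component catalog, and decomposed by
    non-negative matrix factorization with cophenetic rank selection.
    Includes single-sample signature fitting by non-negative least
    squares with bootstrap stability assessment, cohort-level signature
    detection rules, tandem-duplication-phenotype and chromothripsis
    state scores, SBS-96 substitution catalogs, exposure-covariate
    association tests, a synthetic cohort simulator with planted
    mutational processes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
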