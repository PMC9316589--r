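Package: chronoscreen
Title: Time-of-Day Resolved Pooled CRISPR Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPR knockout screens run as a
    factorial timepoint-by-treatment design, as used to map circadian
    (chronochemotherapy) drug-sensitivity genes. Covers exact-match sgRNA
    quantification from FASTQ, median normalization and inter-sample QC, a
    rule-based fold-change set-algebra hit caller that separates
    timepoint-specific drug resistance and sensitivity genes, hypergeometric
    pathway over-representation of the resulting gene sets, and a seeded
    negative-binomial screen simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
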