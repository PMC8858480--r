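Package: comention
Title: Drug Prioritization from Literature Co-Mentions and Signature
    Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks small molecules against arbitrary biomedical search
    terms from drug-PMID co-mention tables, augments the top-ranked
    (unweighted) drug set with additional compounds using two drug-drug
    similarity matrices (pairwise shared-PMID counts and cosine
    similarity of drug-induced expression signatures), and benchmarks
    the rankings with per-term AUROC and average precision against
    shuffled-matrix nulls using the Mann-Whitney U test. Includes seeded
    generators for corpora, association tables, signature matrices and
    term libraries with planted drug-term structure, so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
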