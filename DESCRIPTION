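Package: regnetdiff
Title: Differential Transcription-Factor Targeting from Paired Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers condition-specific transcription-factor (TF) to gene
    regulatory networks by PANDA-style message passing over a binary motif
    prior, a protein-protein interaction prior, and group-specific gene
    co-expression, and quantifies differential TF targeting between two
    paired conditions (e.g. a cell line versus its tissue of origin).
    Provides empirical-Bayes moderated paired differential expression,
    pre-ranked gene-set enrichment with gene-set permutation, TF out-degree
    and gene in-degree comparisons, pathway targeting tests, permutation
    calibrated correlation of expression change versus targeting change,
    ChIP-seq-style promoter peak validation, and a seeded synthetic-study
    generator with planted differential-targeting structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
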