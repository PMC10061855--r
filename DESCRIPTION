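Package: droughtmem
Title: Transcriptional Drought-Memory Analysis for Recurring Dehydration Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting transcriptional drought memory in
    control/first-stress/third-stress (R0/S1/S3) RNA-seq designs. Provides a
    negative-binomial Wald differential-expression caller with median-of-ratios
    normalisation, trajectory-based classification of drought-memory, non-memory
    and late-response genes with the standard eight sign-pattern categories,
    orthogroup Venn partitioning into shared/species/ecotype hierarchies,
    hypergeometric term enrichment, signed Pearson co-expression screening for
    transcription-factor "molecular switch" modules, maximal-clique-centrality
    hub ranking of interaction networks, leaf water-status indices (relative
    water content and water loss), and a seeded synthetic-data generator that
    plants known trajectory categories and switch modules for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
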