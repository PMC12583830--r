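Package: fitscan
Title: Fitness-Guided Saturation Mutagenesis Design and Base-Editing
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for protein engineering guided by per-position amino-acid
    log-probability matrices from zero-shot variant-effect predictors. Scores
    and ranks saturation-mutagenesis variants with an additive log-probability
    fitness score, tests mutation-class enrichment in the top fraction of a
    ranked library, selects candidates by mutation-type quotas, designs
    multi-site combination variants with an exact lazy top-N search over
    additive scores, and quantifies base-editing outcomes (per-position
    conversion, product purity, indels, editing-window profiles and
    fold-change summaries) from amplicon reads. Includes seeded generators for
    synthetic fitness matrices, amplicon read sets and replicate efficiency
    tables so every stage can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
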