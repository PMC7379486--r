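Package: cfgm
Title: Marker-Seeded Coexpression Gene Modules and Preranked Enrichment
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds marker-seeded coexpression gene functional modules from an
    expression compendium (mean Fisher-z correlation to marker genes with a
    per-gene permutation null), ranks two-class expression contrasts by a
    log-fold-change or fixed-prior moderated t statistic, scores module
    enrichment in the ranked lists with a weighted Kolmogorov-Smirnov
    running-sum statistic (random-set permutation null, NES, leading-edge
    extraction), and tests cross-condition overlap of leading-edge core genes
    with the hypergeometric tail test. Includes a seeded synthetic-data
    generator with planted module structure for end-to-end validation, plus
    readers and writers for the GCT, CLS, GMT and RNK text formats and a
    pipeline runner for disease-versus-drug signature-reversal screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
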