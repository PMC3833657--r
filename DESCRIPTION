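Package: oncoannot
Title: Multi-Faceted Annotation of Gene-Cancer Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with sentence-level annotations of gene
    expression changes that co-occur with cancer terms. Provides a typed,
    validated representation of annotation units carrying four concepts
    (change in gene expression, change in cell state, initial gene
    expression level, proposition type), canonical JSONL/TSV corpus I/O,
    dictionary-based longest-match tagging of cancer terms, a ten-rule
    engine that classifies genes as oncogenes, tumor suppressor genes or
    biomarkers together with its first-principles derivation, descriptive
    and inferential corpus statistics (value distributions, contingency
    tables with Pearson residuals, chi-square tests, odds ratios,
    stratified independence tests), inter-annotator agreement metrics
    (simple agreement, Cohen's kappa, G-index) with rule-validation
    scoring, and a seeded synthetic corpus generator for end-to-end
    testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
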