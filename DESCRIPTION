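Package: fmtkit
Title: Microbiome and Clinical Analysis for Oral Fecal Microbiota
    Transplantation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse placebo-controlled fecal microbiota
    transplantation (FMT) trials in dogs with tylosin-responsive
    enteropathy, from the ASV count table onward: feature-table
    filtering and total-sum scaling, taxonomic aggregation, donor-ASV
    engraftment quantification by set exclusion, alpha/beta diversity
    (Shannon, Bray-Curtis, PERMANOVA), bias-corrected compositional
    differential abundance with a per-dog random effect, CCECAI-based
    remission/relapse scoring with fecal consistency and dry-matter
    endpoints, and a Dirichlet-multinomial trial simulator with known
    engraftment and clinical ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    biomformat,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
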