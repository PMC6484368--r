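Package: dqindexr
Title: Indexing and Categorizing Narrative Data-Quality Checks with a Data
    Element-Function Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for indexing heterogeneous narrative data-quality (DQ)
    checks from clinical data research networks under a common data
    element-function model. Each check is reduced to an entity-attribute-value
    triple: the check itself, a construct kind (data element or function), and
    an extracted term. The package provides span-markup annotation input and
    output, a trainable lexicon-plus-context extractor with an iterative
    annotate-train loop, categorization of extracted terms into network
    controlled vocabularies (packaged for the OHDSI and CESR dialects),
    descriptive analyses (domain frequency tables, data element by function
    pairing matrices, Kahn harmonization cross-tabulations, and cross-network
    domain overlap), and a template-based synthetic corpus generator so the
    whole workflow is testable without proprietary check collections.
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
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
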