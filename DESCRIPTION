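Package: coiauth
Title: COI DNA Barcoding Authentication of Seafood Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for species authentication of seafood
    products by COI (Cytochrome Oxidase I) DNA barcoding. Provides amplicon
    quality control with NUMT (nuclear mitochondrial pseudogene) screening via
    six-frame translation under the vertebrate mitochondrial genetic code,
    percent-identity species assignment against a local, taxonomy-annotated
    reference panel by optimal global alignment, a regulatory trade-name
    compliance engine for calling product misdescription, and stratified
    misdescription statistics for geographic market surveys. Ships a
    machine-readable transcription of a 60-product Italian sushi survey as a
    worked fixture, and a seeded synthetic-data generator producing reference
    panels, queries at controlled identity, NUMT decoys and whole surveys with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    tools,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
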