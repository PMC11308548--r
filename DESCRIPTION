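Package: kotrait
Title: Predicting Microbial Functional Traits from KEGG Ortholog Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns per-function binary classifiers of microbial phenotypic
    traits from KEGG-ortholog (KO) copy-number profiles derived from
    taxon-to-function knowledge bases in the FAPROTAX flat-file format.
    Parses functional-group files with set-operation directives, maps taxa
    to an NCBI-style taxonomy, assembles genome-by-KO feature and
    genome-by-function label matrices, tunes logistic regression, random
    forest, support vector machine and neural-network classifiers by nested
    stratified cross-validation with Matthews-correlation model selection,
    predicts traits for new (possibly incomplete) genomes, extracts
    function-associated genes from fitted models, simulates genome
    fragmentation at target completeness levels, and supports user-curated
    refinement of functional classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    withr,
    jsonlite,
    glmnet,
    ranger,
    e1071,
    nnet,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
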