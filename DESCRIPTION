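Package: PAEzone
Title: Parsimony Analysis of Endemicity and Faunistic Zonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for parsimony analysis of endemicity (PAE): building binary
    areas-by-species presence-absence matrices from occurrence records,
    maximum-parsimony area-cladogram search under Fitch parsimony with
    TBR/SPR/NNI branch swapping, strict and majority-rule consensus,
    nonparametric bootstrap support, ensemble fit indices (CI, RI, RC, HI),
    random-tree length distributions, detection of areas of endemism, and
    extraction of nested zone/subzone schemes from the rooted area cladogram.
    Includes a synthetic-data generator with known hierarchical area structure
    so every stage of the pipeline can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
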