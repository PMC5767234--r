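Package: cotracer
Title: Producer Assignment for Co-Culture-Induced Metabolites by 13C
    Dynamic Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for deciding which organism in a microbial
    co-culture produces each induced LC-MS metabolite feature, using 13C
    dynamic labeling of the separated mono-cultures. Implements induced-feature
    detection from feature tables, isotopologue ladder extraction from
    centroided spectra, matrix-based natural-isotope-abundance correction by
    non-negative least squares, total 13C-incorporation and replicate t-test
    statistics, producer assignment with supernatant-dependence and
    physical-interaction flags, local molecular networking by the modified
    cosine score, and a seeded synthetic-data generator that emulates
    LC-QTOF-MS measurements of a two-fungus co-culture experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    mzR,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
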