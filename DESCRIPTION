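Package: orientia
Title: Search-Query Temporal-Orientation Indices and Ecological Panel Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring a population's temporal orientation from
    search-engine query volumes and relating it to region-level health
    outcomes. Implements Trends-style normalization of query counts to a
    0-100 index, past- and future-orientation ratio statistics per
    region-year, assembly and diagnostics (summary moments, correlation
    matrix with p-values, variance inflation factors) of a region-year
    panel, ordinary least squares inference with exhaustive all-subsets
    AIC/BIC model comparison and a forward-with-purge stepwise check, and
    a seeded synthetic-data generator that emulates the joint structure of
    monthly year-phrase query counts, socio-economic covariates and
    suicide-rate outcomes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
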