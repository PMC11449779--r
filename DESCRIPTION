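Package: pcontinuum
Title: Genetic Continuity of the General Psychopathology Factor in Family
    and Twin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether mild, moderate and extreme
    elevations of a general psychopathology (p) factor share one genetic
    etiology.  Simulates sibling and twin family data from a
    liability-threshold bifactor model with additive-genetic, shared- and
    nonshared-environment components; estimates the bifactor measurement
    model from binary diagnoses (tetrachoric correlations, principal-axis
    extraction, oblimin rotation, Schmid-Leiman orthogonalization, Tucker
    congruence); computes the item-response-theory conditional reliability
    of the diagnostic sum score; runs sibling familial-coaggregation
    regressions with linear-by-linear trend and lack-of-fit tests and an
    intellectual-disability negative control; and fits classical ACE twin
    models together with DeFries-Fulker extremes analyses of group
    heritability across proband thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    lmtest,
    sandwich,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
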