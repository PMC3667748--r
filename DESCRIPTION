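Package: sfsmix
Title: Strong Purifying Selection from Extended Site Frequency Spectra
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the fraction of sites under strong purifying selection
    from deep population polymorphism data by maximum likelihood on the
    folded site frequency spectrum extended with the monomorphic
    (zero-frequency) class. A test class of sites (four-fold degenerate
    synonymous positions) is fit jointly with a neutral reference (short
    intron interiors) under a mixture of neutral, weakly and strongly
    selected categories using the Wright stationary density with binomial
    sampling to the sample depth. Includes a matched-pair bootstrap that
    controls GC content and regional mutation-rate variation when
    estimating missing polymorphism, an optional shared per-frequency-class
    correction absorbing demography, stratified group estimates, and a
    synthetic site-table generator that emulates the statistical structure
    of deep Drosophila panel data for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
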