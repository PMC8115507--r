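Package: pondwi
Title: Ponding-Persistence Wetness Index Mapping of Malaria Vector Larval Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates daily gridded surface-layer soil saturation under
    seasonal rainfall and rotating sprinkler irrigation with a conservative
    bucket model and D8 surface routing, converts saturation into a
    ponding-persistence Wetness Index, calibrates the ponding saturation
    threshold against larval-habitat survey points by maximizing the
    probability of detection with bootstrap resampling, and derives habitat
    statistics: per-cell exceedance-probability maps, stream-flow masking,
    fractional-coverage time series with monthly means and confidence
    intervals, habitat stability classification, and baseline-versus-
    irrigation scenario comparisons with rank-sum and Welch tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
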