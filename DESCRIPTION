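Package: sedcea
Title: Cost-Effectiveness Analysis of Pediatric MRI Sedation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness modelling of sedation strategies for
    children undergoing magnetic resonance imaging under the Japanese public
    healthcare payer perspective. Provides a generic decision-tree engine with
    expected-value rollback and a path-enumeration oracle, a parameter registry
    with beta/gamma/normal distributions fitted from published means, confidence
    intervals and ranges, construction of a five-strategy sedation model with
    rescue cascades and itemized costs, incremental cost-effectiveness ratios
    with absolute and extended dominance classification, one-way deterministic
    sensitivity and threshold analysis, Monte Carlo probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and random-effects
    pooling of success proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    metafor
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
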