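Package: tintr
Title: Chronology of Retroposon Activity from Nested Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects unambiguously nested retroposon insertions
    (transpositions in transpositions) in RepeatMasker annotation
    reports, assembles them into a directional insertion-count matrix,
    and fits a probabilistic Gaussian activity-period model by maximum
    likelihood to recover the relative chronological order of retroposon
    subfamily activity. Includes a forward simulator of nested
    retroposition with known ground truth, an activity-interval chart
    renderer, and command-line entry points for reproducible pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
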