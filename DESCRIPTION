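Package: autovalidr
Title: Autovalidation Rule Engine for Clinical Laboratory Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable autoverification (autovalidation) rule engine for
    post-analytical release of clinical laboratory test results. Every result
    is evaluated against a conjunctive rule set: patient demographics,
    analyzer flags, hemolysis/icterus/lipemia interference indices,
    autovalidation range, critical limits, delta check (absolute, percent,
    rate-of-change and reference-change-value modes), cross-test consistency
    ratios and internal quality control gating. Includes utilities to derive
    autovalidation and delta limits from historical result distributions, a
    two-phase verification harness that generates boundary test cases and
    measures manual-versus-automatic concordance without releasing any
    result, and a seeded synthetic result-stream generator with preanalytical
    error injection (sample swaps, intravenous dilution, hemolysis) for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lubridate
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
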