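Package: crctnm
Title: Rule-Based Extraction of Colorectal Cancer Status and TNM Stage
    from Free-Text Clinical Reports
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects whether free-text imaging and histopathology reports
    describe current primary colorectal cancer, and extracts explicitly
    written TNM staging values (with prefixes, substages and the Kikuchi
    and Haggitt levels) from anywhere in the report while guarding against
    look-alike false positives such as MRI sequence names and vertebral
    levels. Includes a ConText-style modifier scoping engine (negation,
    temporality, metastasis, recurrence, treatment response), a synthetic
    clinical-report generator with exhaustive ground truth, an evaluation
    harness computing micro-averaged PPV, NPV, sensitivity and specificity
    with 95% Wilson score intervals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
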