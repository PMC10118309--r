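Package: flexcrit
Title: Fixed and Flexible Decision Criteria in Signal Detection Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing how perceptual decision criteria relate to
    sensory uncertainty. Implements equal-variance signal detection theory for
    detection tasks (discriminability, relative and absolute criteria, the
    Bayes-optimal criterion), a family of noise-dependent criterion-setting
    policies, and the solution-space analysis showing that a matched-d' lower
    relative criterion under inattention is consistent with an infinite family
    of absolute-criterion policies. Provides a seeded simulator for detection
    and embedded-category (unequal category variance) observers, the ideal
    observer boundary for the embedded-category task, and maximum-likelihood
    recovery of the absolute criterion and measurement noise from trial data,
    the task design under which the absolute criterion becomes identifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
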