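Package: dsagree
Title: Agreement Analysis for Heat-Flux Double-Sensor Core Temperature
    Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation toolkit for non-invasive heat-flux double-sensor
    core body temperature monitoring against an esophageal reference
    during targeted temperature management (TTM). Implements the
    steady-state heat-flux sensor model and its inverse, a synthetic TTM
    cohort simulator (induction, 33 degree C maintenance, 0.25 degree
    C/h rewarming, 37 degree C hold) with per-patient bias, lag,
    artifacts and dropouts, time-matching of a 1 Hz sensor stream
    against a 30-minute reference, a pooled 2-SD artifact filter, and
    the method-comparison statistical battery: paired t-test,
    Bland-Altman bias and limits of agreement with confidence intervals,
    two-way mixed-effects intraclass correlation (single measure,
    consistency or absolute agreement) with F-based confidence intervals
    and Cicchetti classification, coverage within an a-priori threshold,
    and exact F-distribution sample-size and power calculations for ICC
    reliability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
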