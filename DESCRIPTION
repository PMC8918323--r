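Package: assistscreen
Title: Real-Time Consistency Screening for Repeated ASSIST Administrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting invalid (careless, random, or fraudulent)
    responding in two-stage online recruitment designs that administer the
    WHO ASSIST cannabis subscale twice: once at eligibility screening and
    again at baseline. Provides the instrument definition and scoring engine,
    an eleven-check consistency rule engine that compares the two
    administrations and screens out inconsistent respondents, a recruitment
    pipeline with conserving consort-flow accounting, a synthetic-respondent
    simulator with configurable mixtures of faithful, random, straightlining
    and eligibility-seeking behaviours, and an analysis layer producing
    group comparisons, inconsistency frequency tables and detection
    performance summaries against simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
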