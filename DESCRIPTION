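Package: encapr
Title: Response-Surface Optimization and Release Kinetics for
    Microencapsulation Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for formulation optimization of spray-dried
    microcapsules: construction and validation of central composite
    designs, computation of encapsulation responses (yield, efficiency,
    loading capacity), second-order response-surface regression on coded
    factors with lack-of-fit ANOVA, Derringer-Suich multi-response
    desirability optimization, and in-vitro release-kinetics model
    fitting and selection (zero-order, first-order, Higuchi,
    Korsmeyer-Peppas) with transport-mechanism classification. Ships the
    13-run quebracho-tannin encapsulation study tables as a worked
    fixture and seeded simulators for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
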