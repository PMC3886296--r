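Package: ruam
Title: RAND/UCLA Appropriateness Method Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the RAND/UCLA Appropriateness Method (RUAM), a
    modified Delphi procedure in which an expert panel rates the
    appropriateness of treatments for permuted clinical scenarios on a
    9-point scale.  The package enumerates scenario spaces from declarative
    configurations, validates long-format panel rating tables, classifies
    each (scenario, treatment) indication as appropriate, uncertain or
    inappropriate using the standard median-band, agreement and
    disagreement rules, produces summary analytics (appropriateness
    distributions, agreement rates, preferred-option shares,
    discriminative-factor scores), simulates complete synthetic panel
    rounds with planted ground truth, and exports patient-profile
    decision-support lookups as JSON.  The shipped default configuration
    describes the management of iron deficiency (with or without anaemia)
    in inflammatory bowel disease.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
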