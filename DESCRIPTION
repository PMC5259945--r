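Package: diadem
Title: Linked Diabetes-Depression Care-Pathway Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete-event simulation of the care pathway for
    adults with type-2 diabetes and comorbid depression. Couples a depression
    natural-history model (onset, minor-to-major progression, spontaneous
    recovery, relapse) with a pluggable diabetes complication and mortality
    engine through a bi-directional hazard linkage, and layers primary-care
    contact processes, opportunistic and annual-review depression screening
    with imperfect test characteristics, and a treatment pathway with
    collaborative-care modifiers on top. Accumulates costs by category,
    utilities, QALYs and societal day counts with discounting, and evaluates
    four care-pathway policies (current practice, collaborative care,
    universal opportunistic screening, and their combination) with common
    random numbers, incremental cost-effectiveness analysis and a univariate
    sensitivity-analysis harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
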