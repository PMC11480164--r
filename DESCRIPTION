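Package: fmrad
Title: Formal-Methods Classification of Radiomic Feature Series
Version: 0.1.0
Authors@R:
    person("fmrad", "maintainers", email = "fmrad@example.org", role = c("aut", "cre"))
Description: Rule-based classification of per-slice radiomic feature series by
    model checking. Feature values are discretized into five equal-width ordinal
    levels, each patient's slice series is encoded as a linear labeled
    transition system (serialized in CCS process-algebra syntax), and a modal
    mu-calculus model checker decides whether an exemplar-derived formal
    property (the diagnostic rule) is satisfied. Includes rule synthesis from
    radiologist-designated exemplar patients, diagnostic performance
    evaluation (confusion matrices, combined model-plus-reader adjudication),
    a seeded synthetic cohort generator emulating a mild-acute-pancreatitis
    CT study, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
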