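Package: guhapaths
Title: GUHA Association Mining of Paths to Premature Mortality in Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploratory mining of multi-predicate associations
    ("paths") with premature death in longitudinal cohort data, in the GUHA
    (General Unary Hypothesis Automaton) tradition. Computes an individual
    life-table-based premature-death outcome with a configurable buffer
    period, binarizes cohort attributes into mutually exclusive Boolean
    predicates, enumerates antecedent conjunctions with support pruning, and
    evaluates them against the outcome with the Above Average generalized
    quantifier and the one-sided Fisher exact quantifier. Includes task
    schedules with cross-task deduplication and predicate-frequency
    summaries, a Beta-Binomial Monte-Carlo posterior for each path's
    prevalence ratio, and a synthetic-cohort generator with planted
    associations for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
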