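Package: toxflow
Title: Longitudinal Tolerability Trajectories, Sankey Flows, and the Toxicity Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns longitudinal clinical-trial adverse-event (CTCAE) and
    patient-reported-outcome observations into cohort selections, Sankey flow
    graphs, Toxicity Index summaries, grade-duration tables, and plain-language
    final-state summaries. Includes a long-format CSV ingest layer with
    user-defined time and response orderings, a first-order Markov trial
    simulator with CTCAE-like and PRO-like presets, and a command-line
    interface mirroring the explorer workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
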