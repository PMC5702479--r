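Package: iscnet
Title: Dynamic Intersubject Correlation Networks for Threat Approach and Retreat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic intersubject correlation (ISC) network analysis
    of continuously modulated threat. Implements leave-one-subject-out
    intersubject correlation matrices (per subject, group-averaged and
    symmetrized, and per time slice), within- and between-network connection
    weights with positive-only, negative-only and diagonal-inclusive variants,
    slope estimation on weight trajectories, and circular-shift permutation
    inference with null-mean correction. Ships a simulator of the moving-circles
    threat paradigm (momentum-smoothed random motion, block schedules, collision
    shocks) and a multi-subject synthetic BOLD-like generator with known
    ground-truth coupling dynamics, so every stage of the pipeline can be
    exercised and validated without real neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
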