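Package: replaytdlm
Title: Replay Sequenceness Analysis for Mental Program Execution with Synthetic MEG
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline for studying fast
    neural replay during mental program execution. Provides a deterministic
    task-program world (a directed graph of 12 locations whose operations act
    on a 3-bit cartoon-face data structure), a synthetic sensor-space MEG
    generator with injected replay sequences and ground-truth injection logs,
    lasso logistic decoders for objects, face attributes and abstract
    operations, two-stage temporally delayed linear modeling (TDLM) of
    sequenceness with permutation nulls and multi-step extensions,
    replay-onset detection, event-locked reactivation contrasts, and
    time-resolved GLM representational similarity analysis. The acceptance
    surface is parameter recovery of injected effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
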