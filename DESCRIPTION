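Package: memgate
Title: Recall-Gated Systems Consolidation of Synaptic Memories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and semi-analytic theory toolkit for recall-gated
    systems consolidation of memory. Implements population models of synaptic
    plasticity (binary switch, cascade, multivariable chain), ideal-observer
    recall signal-to-noise ratios and forgetting curves, structured memory
    streams with Poisson/Weibull/deterministic recurrence of reliable
    memories, short-term-memory-gated long-term consolidation with threshold,
    band and ensemble gating functions, and semi-analytic computations of
    consolidation probability, induced long-term interarrival statistics and
    learnable timescale. Includes task-level demonstrations (supervised
    Hebbian classification, three-factor reinforcement learning,
    autoassociative storage with a familiarity readout) and experiment
    protocols for spacing effects, sparse coding levels and consolidation-rate
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
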