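Package: fvmsim
Title: Agent-Based Force Vector Model of Social Influence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic agent-based simulator for a force vector model of
    opinion dynamics in a continuous attribute space. Agents are attribute
    vectors carrying an active mass ("charisma") and a passive mass
    ("resistance"); pairwise influence follows an inverse-square force law
    whose sign is set by the dot product of the agent vectors and which is
    gated by a bounded-confidence radius (the Attribute Influence Bound).
    Agents closer than a coalescence radius merge into permanent groups.
    Provides adaptive time stepping, initial-condition samplers with
    rejection, geometry presets, per-iteration observables (center of
    attributes, mean distance to closest neighbor, angular sector histograms,
    force decomposition), and ensemble drivers for confidence-bound sweeps,
    agent-decay fits, final-state geometry statistics and consensus grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
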