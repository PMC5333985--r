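Package: bcrsim
Title: Stochastic Simulation of B-Cell Clonal Selection Driven by BCR Saturation
Version: 0.1.0
Authors@R:
    person("bcrsim", "developers", email = "bcrsim@example.org", role = c("aut", "cre"))
Description: A seedable discrete-time simulator of B-cell clonal homeostasis on
    an antigen-concentration by affinity plane. Clonal fates (death, quiescence,
    proliferation, receptor editing, isotype switching, somatic hypermutation,
    memory and plasma-cell differentiation) are driven by B-cell receptor (BCR)
    occupancy computed from two-component mass-action equilibrium, under
    niche-specific antigen-pool dynamics that distinguish depletable
    compartments (bone marrow, follicles, germinal centers) from the
    inexhaustible blood pool. Includes a germinal-center mutation-selection
    engine with capture-proportional divisions, repeated-immunization
    schedules, a synthetic antigen-panel generator, trajectory and phase-map
    output, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
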