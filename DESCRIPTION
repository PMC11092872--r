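Package: prewetting
Title: Lattice Monte Carlo and Mean-Field Models of Polymer Collapse
    Coupled to Bulk Phase Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a single long, collapsible self-avoiding polymer on a
    periodic cubic lattice coupled to phase-separating bulk mixtures, and
    solves the matching coupled Landau mean-field theory. The Monte Carlo
    engine implements bond addition/removal/kink moves for the polymer
    (BFACF-style bond translation with exact Hastings corrections), kink,
    reptation and grand-canonical reservoir-exchange moves for a two-species
    short-chain bulk, and single-site spin flips for a minimal lattice-gas
    bulk. The mean-field module evaluates and minimizes the coupled free
    energy over polymer density and bulk order parameter, locates continuous
    and first-order collapse transitions, and computes quadratic-branch
    approximations and the effective excluded volume. Exact small-system
    enumeration oracles validate the samplers. Observables include radius of
    gyration, on-polymer bulk density difference, occupancy profiles and
    contact maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
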