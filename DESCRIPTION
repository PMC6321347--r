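Package: mechkit
Title: Graph-Theoretic Reaction Discovery and Statistical-Rate Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trajectory-based reaction mechanism analysis: bond
    detection from Cartesian geometries via covalent-radius adjacency matrices,
    Laplacian fragment counting and SPRINT spectral descriptors, detection of
    bond breaking/formation events along molecular dynamics trajectories with
    extraction of transition-state candidate geometries, spectral deduplication
    and van-der-Waals prescreening of candidates, canonical (Eyring TST) and
    microcanonical (RRKM) rate constants with Beyer-Swinehart direct state
    counting and an optional Eckart tunneling correction, and stochastic
    solution of the chemical master equation on reaction networks by Gillespie
    kinetic Monte Carlo, including branching-fraction scans and empirical
    reaction-order fits. A synthetic fixture generator produces trajectories
    with scripted bond events and toy networks with analytically known kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    deSolve,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
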