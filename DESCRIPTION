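Package: ricciflock
Title: Discrete Ricci Curvature-Driven Collective Motion on Vietoris-Rips Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator for curvature-driven flocking in periodic
    two- and three-dimensional boxes. At every time step the swarm is embedded
    in a weighted Vietoris-Rips complex; agents steer towards the headings of
    the most negatively Forman-Ricci-curved neighbours found in an annular
    (local or non-local) region, rather than averaging over a metric ball as
    in the classical Vicsek model. Includes the topological observables used
    to characterise such swarms: polar order parameter, mean Forman-Ricci
    curvature, Hodge Laplacian spectral entropy, Betti numbers, Euler
    characteristic and the radial distribution function, together with a
    metric Vicsek baseline, parameter sweeps and a small command-line
    interface for standalone point-cloud analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
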