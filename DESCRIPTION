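Package: mitojam
Title: Agent-Based Simulation of Mitochondrial Transport and Jamming in Axons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates bidirectional, motor-driven mitochondrial transport in an
    axonal segment. Mitochondria are overdamped self-propelled bead-spring
    chains with stochastic fission and fusion, coupled through a purely
    repulsive contact potential to a triangulated membrane and membrane
    periodic skeleton tube that can be held fixed or allowed to deform.
    Provides the jamming observables used to characterise transport
    disruption (ensemble axial speed, relief time, nematic order parameter,
    shape factor, radial membrane dilation), sigmoid fits of relief times
    against lifecycle rates, and fission-fusion phase diagrams, plus
    trajectory, XYZ and VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
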