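Package: axomito
Title: Agent-Based Simulation of Mitochondrial Transport, Jamming, and Swelling in Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bidirectional, motor-driven mitochondrial transport in a
    cylindrical axonal segment. Mitochondria are self-propelled bead-spring
    chains with harmonic bending and stretching, Hookean steric exclusion, and
    stochastic fission/fusion lifecycle dynamics; the axonal boundary is a
    triangulated membrane coupled to a periodic actin-spectrin skeleton and can
    be held rigid or allowed to deform under organelle contact forces
    (Weeks-Chandler-Andersen repulsion). Includes analysis metrics for
    transport disruption: ensemble axial speeds, jamming relief time, nematic
    order along the axon axis, per-chain shape factor, chain-length statistics,
    and maximal radial membrane dilation, plus deterministic fixture
    generators and plain-text trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
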