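Package: spintip
Title: Tipping Points of Networked Spin Systems on Degree-Mixed Random
    Graphs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates critical transitions in networked spin systems.
    Random multigraphs are built from degree sequences with the
    configuration model (uniform stub pairing, self-loops and multi-links
    retained), driven through quasi-static external-field sweeps with an
    asynchronous Metropolis-style Ising dynamic, and the resulting
    hysteresis transition curves are reduced to tipping points. Tools are
    provided to enumerate controlled degree substitutions between two or
    more degree types, to map how the tipping point depends on the average
    degree of a degree-mixed network, to fit parabolic tipping-boundary
    curves, and to classify tipping intersections and forbidden tipping
    regions. Includes a mean-field self-consistency solver as an analytic
    reference for the pitchfork and hysteresis bifurcations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
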