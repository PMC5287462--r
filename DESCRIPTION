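Package: mfstab
Title: Mean-Field Stability Analysis and Targeted Stabilization of
    Spiking Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mean-field analysis of networks of leaky integrate-and-fire
    neurons described at the population level by indegree and synaptic
    weight matrices. Computes the stationary Siegert gain function under
    the diffusion approximation (with the linear-order synaptic filtering
    correction), finds stable and unstable fixed points of the
    self-consistent rate equations by pseudo-time integration and
    bisection of the external drive, decomposes the linear response into
    eigenmodes of the effective connectivity, and derives minimal,
    anatomically constrained indegree modifications that preserve the
    basin of attraction of a low-activity state when the external drive
    is increased.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
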