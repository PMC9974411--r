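Package: lpneuro
Title: Robustness Analysis of a Four-Compartment Lateral Pyloric Neuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conductance-based, four-compartment model of the crustacean
    stomatogastric lateral pyloric (LP) neuron (axon initial segment,
    soma-primary neurite, secondary and tertiary neurites), driven by periodic
    graded inhibition from its pyloric-network partners (AB, PD, PY), together
    with the machinery to study the robustness of its rebound-bursting
    phenotype: a declarative gating-kinetics registry, ohmic and
    Goldman-Hodgkin-Katz current kernels, a fixed-step semi-implicit
    integrator with exponential gate updates, a five-way firing-pattern
    classifier, Monte-Carlo conductance-perturbation protocols, and axial
    resistivity (Ra) sweeps that rescale the axon-to-soma coupling resistor.
    Includes a synthetic-population generator that samples, screens and bounds
    parent models so the perturbation experiments run end to end without
    external model databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
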