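Package: ebccsim
Title: Olivocerebellar Spiking Network Simulation of Eye-Blink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates eye-blink classical conditioning (EBCC) with a spiking
    model of the olivocerebellar microcircuit (mossy fibers, granule and Golgi
    cells, Purkinje cells, molecular-layer interneurons, deep cerebellar
    nuclei and inferior olive). Neurons are extended generalized
    leaky integrate-and-fire (E-GLIF) point models with adaptation and
    spike-triggered depolarizing currents; parallel-fiber to Purkinje-cell
    synapses are plastic under a supervised spike-timing rule driven by the
    inferior-olive teaching signal. Includes a seeded statistical connectome
    generator, the paired CS/US stimulation protocol, three dystonia-like
    lesion operators (reduced olivocerebellar input, aberrant Purkinje-cell
    burst firing, imbalanced Purkinje-cell synaptic densities), and the
    spike-density-function behavioral readout (conditioned-response detection,
    timing and block statistics) with the accompanying non-parametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
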