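Package: spikeprune
Title: Unsupervised Spiking Neural Networks with Pruning During Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation of a single-layer unsupervised spiking neural network
    with Poisson rate coding, softmax winner-take-all output firing, and a
    simplified spike-timing-dependent plasticity rule (exponential long-term
    potentiation, constant long-term depression, scaled updates). Implements
    activity-triggered synaptic pruning and soft-pruning applied during
    training, neuron labeling and population-vote prediction, a synthetic
    class-prototype image generator, IDX image/label file input and output,
    and linear weight-to-conductance mapping for memristive crossbar export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
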