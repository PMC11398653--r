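Package: momentcov
Title: Covariance-Based Neural Computation with Moment Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how perceptual information carried by the
    covariance of spiking activity can be computed on by downstream neurons.
    Implements the moment activation of leaky integrate-and-fire neurons
    (closed-form maps from synaptic current mean and variance to output
    spike-count mean, variance and correlation), feedforward moment neural
    networks trained by backpropagation through the moment mappings,
    analytic covariance encoders for drifting-grating and two-channel
    stimuli, reconstruction of spiking networks from trained moment
    networks, spectral and synchrony analyses of population activity, and a
    Monte-Carlo mutual-information breakdown of the readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    MASS,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
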