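Package: snnlab
Title: Noisy Spiking Neural Networks with Latency Coding and STDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of leaky integrate-and-fire (LIF) spiking neural
    networks driven by additive Gaussian white-noise currents, modelled on the
    NEST noise-generator semantics. Provides exact exponential membrane
    integration, latency (rank-order) spike encoding of grayscale images,
    supervised pair-based spike-timing-dependent plasticity (STDP), two- and
    three-layer network builders, a coincidence-gated structural
    synapse-growth experiment, a procedural digit-image generator, an MNIST
    IDX reader/writer, and scripted experiments (rheobase sweep, noise-mean
    accuracy sweep, growth comparison) with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
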