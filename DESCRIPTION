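Package: beevision
Title: Neuromorphic Model of Active Vision in the Bee Optic Lobe and Mushroom Body
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates how scanning flight shapes visual coding in the bee brain.
    A spiking feed-forward pathway (photoreceptors, lamina pooling, leaky
    integrate-and-fire medulla, delay-aligned lobula with plastic lateral
    inhibition) self-organises through non-associative learning (Oja's rule on
    feed-forward weights, symmetric inhibitory STDP on lateral weights) while
    the model scans synthetic naturalistic scenes in five-patch sweeps. The
    resulting sparse, decorrelated lobula code feeds a mushroom-body classifier
    (random Kenyon-cell expansion, single output neuron) trained by dopamine-
    and octopamine-modulated spike-timing-dependent plasticity. Includes
    procedural stimulus generators (plus and multiplication signs, bars,
    gratings, spirals, 1/f scenes with oriented edges), population-coding
    metrics (Treves-Rolls sparseness, angular distance, orientation and
    velocity tuning), and config-driven behavioural experiments with
    nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
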